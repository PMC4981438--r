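# qgmri

Quantitative MRI (qMRI) measures physical tissue parameters — the
longitudinal relaxation time T1 (ms) and the proton density PD (percentage
units, CSF = 100) — instead of weighted contrasts. In secondary progressive
multiple sclerosis (SPMS), diffuse neurodegeneration outside visible lesions
drives disability but is invisible on conventional MRI; elevated gray-matter
PD (replacement of neural tissue by water) and prolonged cortical T1 are
candidate imaging surrogates, and their correlation with the Expanded
Disability Status Scale (EDSS) is the clinically relevant question.

`qgmri` implements the full analysis chain as a tested, reusable R package,
exercised end to end on a synthetic digital-phantom cohort with known ground
truth (11 simulated patients vs 11 controls by default). External NIfTI
volumes and externally produced segmentations can be consumed through the
same interfaces.

## The measurement chain

1. **Variable-flip-angle T1 mapping** — two spoiled gradient-echo volumes
   (TR/TE/α₁/α₂ = 16.4 ms/6.7 ms/4°/24°); the signal equation
   S = PD·sin(b₁α)(1−E₁)/(1−cos(b₁α)E₁)·e^(−TE/T2\*), E₁ = e^(−TR/T1), is
   linearised as S/sin(α) vs S/tan(α) and solved in closed form per voxel.
2. **B1 mapping** — the quotient of a magnetisation-prepared and a reference
   volume is the cosine of the local preparation angle (nominal 45°).
3. **T2\* mapping** — dual-echo log-ratio (TE 4.3/11 ms).
4. **PD derivation** — the equilibrium amplitude corrected for T1, T2\*, B1
   and the receive-coil profile (estimated by a polynomial fit against the
   water content predicted from T1, W(T1) = 1/(a + b/T1)), normalised to
   median 100 pu in CSF.
5. **Synthetic MP-RAGE** (TR/TI = 1900/900 ms) computed voxelwise from the
   maps — same grid, no registration — then Gaussian-mixture segmentation
   into CSF/GM/WM partial volume estimates.
6. **ROIs** — cortex (PVE ≥ 0.95, T1 ∈ [1200, 1600] ms, non-cortical
   structures and lesions excluded, PVE-weighted means), four deep-gray
   structures (3 mm cubic erosion), NAWM (6 mm erosion), whole brain
   (T1 ≤ 1600 ms / PD ≤ 84.44 pu), global gray matter.
7. **Statistics** — Mann-Whitney U group comparisons per ROI × parameter;
   Spearman correlations with EDSS, age, sex and disease duration computed
   only for cells significantly *increased* in patients (the gate), α = 0.05.

## Worked example

```r
library(qgmri)

cfg <- pipeline_config(save_volumes = FALSE, seed = 42)  # 11 + 11 subjects, 64^3 grid
res <- run_pipeline(cfg, out_dir = "run1")
res$report$group_table[, c("roi", "parameter", "patient_mean",
                           "control_mean", "p", "significant")]
```

```
           roi parameter patient_mean control_mean         p significant
1      caudate        pd        82.02        80.05 0.0473072        TRUE
2      caudate        t1      1353.12      1349.39 0.6063178       FALSE
3       cortex        pd        83.53        81.90 0.2426485       FALSE
4       cortex        t1      1420.18      1405.11 0.2703166       FALSE
...
7         nawm        pd        72.21        68.33 0.0001276        TRUE
11     putamen        pd        83.55        79.46 0.0018599        TRUE
14    thalamus        t1      1287.88      1181.62 0.0031810        TRUE
```

Each row compares the PVE-weighted ROI mean between the simulated patient
and control groups (exact Mann-Whitney p at n = 11 + 11). Which cells reach
significance varies between cohort draws — that is the sampling noise of an
n = 11 study, and `power_experiment()` quantifies it: at the configured
whole-GM PD effect (83.6 ± 1.93 vs 80.7 ± 1.60 pu) the test rejects in 93.6%
of 500 replicate cohorts (Monte-Carlo SE 1.1%). `res$report$cor_table` holds the gated EDSS/covariate
correlations (`tested = FALSE` rows were gated out); `table1.tsv` and
`table2.tsv` in the output directory mirror the two tables.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/qgm.R run --config config.yaml --out run1 --seed 42
Rscript inst/cli/qgm.R simulate-cohort --out truth --seed 1
Rscript inst/cli/qgm.R analyze --measurements m.tsv --covariates c.tsv --out rep
```

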