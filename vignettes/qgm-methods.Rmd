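---
title: "Quantitative gray-matter MRI on digital phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative gray-matter MRI on digital phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qgmri` implements a complete quantitative-MRI (qMRI) analysis of gray-matter
T1 relaxation times and proton density (PD) in secondary progressive multiple
sclerosis (SPMS), exercised end to end on a synthetic digital-phantom cohort
whose ground truth is known. This vignette is the package's own account of the
models it uses, the parameters that matter, and the choices that were open.

## The measurement chain

### Variable-flip-angle T1 mapping

Two spoiled 3D gradient-echo volumes are acquired (simulated) at excitation
angles $\alpha_1 = 4°$ and $\alpha_2 = 24°$ with TR/TE $= 16.4/6.7$ ms. The
ideally spoiled steady-state signal is

$$S(\alpha) = \mathrm{PD}\,\sin(b_1\alpha)\,
  \frac{1 - E_1}{1 - \cos(b_1\alpha)E_1}\,e^{-\mathrm{TE}/T_2^*},
  \qquad E_1 = e^{-\mathrm{TR}/T_1},$$

where $b_1$ is the local transmit-field scale (actual over nominal flip
angle). Writing $y_i = S_i/\sin(b_1\alpha_i)$ and $x_i = S_i/\tan(b_1\alpha_i)$
linearises the equation as $y = E_1 x + M_0(1 - E_1)$, so the two-point fit is
solved in closed form per voxel: `slope` $= E_1$ gives
$T_1 = -\mathrm{TR}/\log(\mathrm{slope})$ and the intercept gives the
equilibrium amplitude $M_0$ (which still carries the $T_2^*$ decay at the
acquisition echo time and the receive-coil profile). Voxels with slope outside
$(0, 1)$ or degenerate abscissae are flagged invalid and excluded from all ROI
statistics — never imputed.

B1 errors propagate quadratically here: a transmit field overestimated by a
factor $k$ shortens apparent T1 by roughly $k^{-2}$ (a 5% B1 error is a ~10%
T1 error). The direction and magnitude were fixed by brute-force simulation of
the forward model and are pinned in the test suite.

### B1 mapping

A reference volume after full relaxation and a magnetisation-prepared volume
(nominal preparation angle 45°) are acquired; their quotient is the cosine of
the local preparation angle, so $b_1 = \arccos(S_\mathrm{prep}/S_\mathrm{ref})
/ \alpha_\mathrm{nom}$. The quotient is clamped to $[-1, 1]$ before the
arccosine; voxels with weak reference signal, or with $b_1$ outside a
plausibility window (default $[0.5, 1.5]$), are invalid. Because the method is
a ratio of two acquisitions, it is exactly invariant to PD and to the receive
profile — a property asserted in the tests. The simulator generates all
volumes on one grid and omits relaxation during the preparation sequence, so
no relaxation correction is applied on the mapping side; resampling from the
coarser grids of a real protocol is supported by the reader when external
data are supplied.

### T2* mapping

A dual-echo gradient-echo pair (TE $4.3/11$ ms) gives
$T_2^* = \Delta\mathrm{TE} / \log(S_1/S_2)$. Equal echoes yield an infinite
T2* whose decay-correction factor is exactly 1 — handled, not an error;
signal growing with TE is unphysical and flagged.

### Spoiling correction

Real gradient-echo acquisitions spoil transverse magnetisation imperfectly,
and published corrections are polynomial adjustments of apparent T1 given B1.
The package carries this as a hook — a polynomial in $(T_{1,\mathrm{app}},
b_1)$ whose coefficients load from YAML — with the identity as default, since
the forward simulator is ideally spoiled. Externally calibrated coefficients
for a particular sequence can be substituted without code changes.

### PD derivation and the water-content calibration

The equilibrium amplitude is corrected for $T_2^*$ decay
($\times\, e^{+\mathrm{TE}/T_2^*}$) and divided by the receive-sensitivity
field, then normalised so the median inside the CSF reference mask is exactly
100 pu. The median (not the mean) makes the anchor robust to tail voxels;
normalisation also makes PD exactly invariant to any global scale of the
receive field.

The receive field itself is estimated from the data: the corrected amplitude
divided by the water content predicted from T1 via the empirical relation

$$W(T_1) = \frac{1}{a + b/T_1}$$

is, up to tissue-level deviations, the receive profile times a constant. The
default calibration fixes $a$ and $b$ from two anchors — $W = 1$ at the CSF
anchor $T_1 = 4300$ ms and $W = 0.8444$ at $T_1 = 1600$ ms — by solving the
2×2 linear system, giving $a \approx 0.8908$, $b \approx 469.55$ ms. The
second anchor is what makes the whole-brain PD cutoff (84.44 pu) exactly
consistent with the whole-brain T1 cutoff (1600 ms). Published 3 T
coefficients can be substituted directly.

Two design points deserve emphasis:

* **The fit is restricted to a T1-homogeneous white-matter compartment**
  (default T1 ∈ [600, 1100] ms) rather than the whole brain. True tissue
  water content does not follow the calibration curve exactly per tissue; a
  whole-brain fit would absorb those tissue-wise offsets into spurious
  spatial structure. Within one tissue the ratio is the receive field times a
  constant, so a polynomial fit on that support recovers the field shape
  essentially exactly (the global scale cancels in CSF normalisation). The
  fitted order-3 polynomial is evaluated over the whole grid and normalised
  to median 1 in-brain.
* **Polynomial order 3** suffices for the smooth, low-order fields the
  simulator generates and for typical coil profiles; the order is a
  parameter.

## Synthetic anatomy and segmentation

A T1-weighted MP-RAGE anatomy is computed voxelwise from the estimated maps
with the single-exponential inversion-recovery closed form

$$S = \mathrm{PD}\,(1 - 2e^{-\mathrm{TI}/T_1} + e^{-\mathrm{TR}/T_1}),$$

TR/TI $= 1900/900$ ms, magnitude by default. The input maps are already
corrected for $T_2^*$, so the nominal TE is zero; a full readout-train
steady-state simulation is deliberately avoided — the anatomy only needs a
consistently contrasted image for segmentation, and it shares the exact grid
of the quantitative maps, so no registration exists anywhere in the pipeline.

Segmentation is a three-component Gaussian mixture on in-mask intensities
(EM with k-means initialisation and a variance floor; partial volume
estimates are the posterior responsibilities), components assigned to
CSF/GM/WM by ascending mean intensity. Two practical notes:

* k-means is started from intensity quantiles with the first and last start
  in the distribution tails (0.5% and 99.5%), because CSF is under 1% of the
  phantom's brain volume and purely random starts can miss it.
* The variance floor (0.1% of the intensity range) keeps EM well-posed on
  noiseless, piecewise-constant synthetic images.

One GM class covers cortex and deep gray matter; the deep structures are
separated by labels (phantom truth internally, or an external subcortical
labelling mapped through a configurable code table). Externally produced PVE
maps and brain masks pass through validation instead of the internal
segmenter.

## ROI construction

All thresholds are the protocol's printed values and are configurable:

* **Cortex**: GM PVE map thresholded at PVE ≥ 0.95, minus an exclusion mask
  (deep GM, hole-filled WM, ventricles, optional cerebellum), minus lesions,
  then restricted to absolute T1 ∈ [1200, 1600] ms. Surviving voxels keep
  their PVE value as weight; ROI values are PVE-weighted means.
* **Deep GM** (thalamus, caudate, putamen, pallidum): hemispheres combined,
  eroded with a 3×3×3 mm³ cubic kernel, lesions removed. All four structures
  are treated identically.
* **NAWM**: WM PVE binarised at 0.95 (the cortical threshold, applied
  symmetrically — a documented choice, the protocol states 0.95 only for
  cortex), eroded with a 6×6×6 mm³ kernel, lesions and deep-gray labels
  removed.
* **Whole brain**: parameter-specific CSF exclusion — T1 ≤ 1600 ms for the
  T1 analysis, PD ≤ 84.44 pu for the PD analysis. The parallel phrasing of
  the protocol is ambiguous between parameter-specific and joint masks; both
  are implemented, parameter-specific by default.
* **Global GM ("NAGM")**: voxelwise maximum of cortex weights and binary
  deep-GM membership; disjointness is asserted.

Kernel edges are specified in mm and converted per axis to voxels (nearest
integer, forced odd, minimum 1). On the desk-scale 2 mm grid the 3 mm kernel
therefore rounds to a single voxel (identity) while the 6 mm kernel is a
3-voxel cube; on the 1 mm protocol grid both take their literal sizes.

## Statistics

Group comparisons use the Mann-Whitney U test per ROI × parameter cell: exact
two-sided p by enumeration for combined n ≤ 25 without ties (the study scale,
n = 22, is always exact), normal approximation with tie correction otherwise.
Correlations with EDSS, age, sex (0/1-coded) and disease duration use
Spearman's rank coefficient with the t-approximation p, computed **only** for
cells whose parameter is significantly increased in the patient group
(p < 0.05 *and* patient mean above control mean). The directional gate
mirrors the study's framing; a two-sided gate is available. No
multiple-testing correction is applied by default, again mirroring the
design; a Holm option exists. Gate soundness — no correlation row for any
non-gated cell — is a tested invariant.

## The phantom cohort

The generator defines the study conditions rather than emulating anatomy:
concentric analytic shapes (a cortical shell, WM core, bilateral ventricles
and four bilateral deep-gray ellipsoids, optional spherical WM lesions) on a
64³ grid at 2 mm isotropic by default, with a configuration for the 1 mm
protocol grid (256 × 224 × 160). Per-tissue T1/PD values are drawn from
group Gaussians whose means and SDs are the published group statistics of
the emulated SPMS cohort (11 patients, 11 controls), e.g. cortex PD 83.8 ±
1.91 pu in patients vs 80.8 ± 1.67 pu in controls; CSF is the 100 pu anchor.
T2* is a fixed per-tissue constant at 3 T values. Lesions (patients only)
get mildly prolonged T1 (1500 ± 80 ms) and raised water content (86 ± 2 pu) —
plausible values, as the emulated study does not report lesion parameters.

Patient EDSS is a truncated Gaussian (mean 5.8, SD 1.88, range 3–8.5,
rejection-sampled) rounded to the 0.5-step granularity of the scale. The
disability link is linear: cortical and deep-gray tissue values are shifted
by `link_slope × (EDSS − mean EDSS)` plus optional Gaussian link noise. The
emulated study reports *observed* rank correlations (about 0.6–0.8), not a
generative model, so the link is a stand-in with free slopes; the defaults
(14 ms and 1.0 pu per EDSS point) give a population rank correlation of
roughly 0.7 for cortical values. Because the link adds variance on top of
the group Gaussian, the configured SDs are the SDs of the *unlinked* draw;
distributional-recovery checks therefore run with the link off.

What the phantom does **not** model: cortical folding and atrophy (the claims
exercised are parameter-level, not shape-level), Rician noise (additive
Gaussian is adequate at the simulated SNRs), coil-array geometry, motion,
distortion, k-space effects, imperfect spoiling, and relaxation during the B1
preparation. Passing tests therefore validate the estimation and analysis
chain, not the acquisition physics of a real scanner.

## Numerical choices and problem sizes

* Noise default `noise_sd = 0.05` in signal units (PD scaled 0–100; VFA
  signals are ≈ 5 units, i.e. SNR ≈ 100 on the 2 mm grid).
* Invalid voxels are excluded, never imputed; empty ROIs are flagged
  measurements, excluded from statistics, and a warning rather than a crash.
* Determinism: every random stream (cohort, lesions, noise, segmentation)
  derives from one master seed; reruns are byte-identical, which the test
  suite asserts at the report level.
* Monte-Carlo validation sizes: 500 replicates for type-I calibration and
  power at the study's effect size (the whole-GM PD cell rejects in ≥ 85% of
  replicates at n = 11 per group), 100–200 replicates for link-correlation
  checks, 2000 subjects per group for distributional recovery. These sizes
  keep Monte-Carlo standard errors comfortably below the margins they test.

## Known limitations

* The internal segmenter is intensity-only (no spatial prior or bias-field
  model); it is adequate because the synthetic anatomy is bias-free by
  construction. Real data should use external PVE maps through the same
  interface.
* Thresholded PVE selection couples segmentation to parameter noise: voxels
  whose estimated PD is high are slightly brighter on the synthetic anatomy
  and slightly more likely to pass the 0.95 cut. At the default SNR this is
  a sub-percent effect, but it is intrinsic to threshold-based ROI
  definitions on synthesized anatomies.
* The Fatouros-style calibration is empirical; per-tissue departures of true
  water content from the curve are exactly why the receive-field fit is
  restricted to a homogeneous compartment.
* The EDSS link is a modelling convenience, not an estimate of biology; only
  its monotonicity and rough strength are meaningful.
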