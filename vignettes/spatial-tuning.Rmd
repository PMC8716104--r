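---
title: "Fine-scale spatial tuning along a cortical axis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale spatial tuning along a cortical axis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facegrad)
```

## The scientific question

Category-selective regions of human ventral temporal cortex — the fusiform
face area (FFA) and occipital face area (OFA) among them — span roughly a
centimetre of cortex. Within such a region, are responses to different
object parts (for faces: eyes, nose, mouth, hair, chin) spatially organised,
or homogeneously mixed? High-field fMRI at ~1 mm resolution can in principle
resolve such fine-scale structure, but testing for it requires a chain of
careful steps: reliable per-condition response estimates, a region
definition uncontaminated by draining veins, removal of the response pattern
shared by all conditions, and a way to align spatial structure across
subjects whose regions differ in shape and position.

`facegrad` implements that chain as a reusable, fully tested pipeline. The
alignment device is an **anatomical axis**: a posterior-to-anterior line
drawn along a sulcal landmark (the mid-fusiform sulcus for FFA, the
occipitotemporal sulcus for OFA). Each vertex's response is projected onto
the axis, giving a 1-D response profile per condition, and the hypothesis
"eyes posterior, mouth anterior" becomes a simple, sign-predicted statistic:
the Pearson correlation between the per-vertex eyes-minus-mouth response
difference and the arc-length position (posterior = smaller position). A
negative correlation means a posterior eye bias.

Because the subject-level imaging data behind published numbers of this kind
are not reproducible at desk scale, the package is validated
property-based: a synthetic-data module plants known structure (gradients,
veins, receptive fields) and every pipeline stage must recover it under the
study's design constants.

## The generative model

`ground_truth()` + `simulate_betas()` generate per-voxel condition
responses on a regular cortical patch (default 12 x 12 vertices at 1.2 mm
pitch, the voxel size of a high-field protocol):

$$\beta_c(v) = b(v) + \mu_c + s_c\,(p(v) - \bar p) + \varepsilon_v,\qquad
\varepsilon_v \sim \mathcal N(0, \sigma^2)$$

* $b(v)$ — a smooth **shared baseline pattern** (a centred Gaussian bump by
  default), standing in for the intrinsic BOLD sensitivity profile that all
  conditions ride on (vascular density, coil sensitivity, partial
  voluming). It is what the shared-pattern regression must remove.
* $\mu_c$ — the condition's mean amplitude in percent signal change (PSC).
  Defaults plant the amplitude ordering typical of face-part experiments:
  whole faces highest (1.5), eyes = mouth (1.2) above nose/hair/chin
  (0.7–0.8), everyday objects lowest (0.5).
* $s_c$ — the planted **gradient** in PSC per mm along the axis; defaults
  `eyes = -0.1`, `mouth = +0.1` encode the eyes-posterior hypothesis.
  Gradients are linear because the statistic of interest is a linear
  correlation and observed profiles are monotone; the gradient multiplies
  the *centred* position so that $\mu_c$ remains the condition's mean
  amplitude (the correlation statistic is invariant to this affine choice).
* **Vein voxels** — a configurable subset gets its face-condition response
  raised to 6% PSC, above the 4% exclusion threshold by construction, so
  the vein filter's behaviour is testable exactly.
* Noise is i.i.d. Gaussian per voxel and scan. Residual noise after
  physiological-noise removal is not well characterised in the literature,
  so the simplest model that supports the recovery tests is the default; an
  AR(1) option (`ar1`) exists for sensitivity analyses but defaults off.
  The noise SD is a free parameter, not a calibrated value — within-ROI
  noise levels are not published for this kind of protocol.

`simulate_timeseries()` turns betas into block-design BOLD series
($y = X\beta + \varepsilon$, baseline signal 100 so that betas are in PSC
units), under the emulated design: 16 s blocks, two per condition per run,
16 s fixation at the start, middle and end, TR 2 s, 8 runs, 7 conditions.

What the generator does **not** emulate: cortical folding (the patch is
flat), spatially correlated noise, motion, distortion, slice timing, or
draining-vein point-spread. Passing tests therefore demonstrate that the
*analysis* is correct and well calibrated under its stated assumptions, not
that those assumptions hold in any given acquisition.

## Estimation: HRF, design, GLM

The haemodynamic response is the two-parameter gamma variate
$h(t) = ((t-\delta)/\tau)^2 e^{-(t-\delta)/\tau}$ for $t \ge \delta$
(zero before), with $\delta = 2.25$ s and $\tau = 1.25$ s — the convention
of the classic block-design fROI toolchain. The exponent is fixed at 2, so
the peak falls at $\delta + 2\tau = 4.75$ s. The HRF is scaled to unit
peak; unit area is available (`scale = "area"`) and only rescales all betas
by a common factor. Condition regressors are boxcars matched to stimulus
duration, sampled on the TR grid, convolved with the sampled HRF, and
truncated to the run — a construction that is exactly checkable against a
brute-force discrete convolution.

`fit_glm()` is ordinary least squares per voxel with an explicit rank check
(a deficient design errors rather than silently pseudo-inverting). Percent
signal change follows the standard convention $100\,\beta_c / \beta_0$ with
$\beta_0$ the intercept estimate; it is undefined (NA) where the baseline
estimate is not positive. No drift regressors are included by default —
intensity normalisation is assumed done upstream — but polynomial drift
columns are available (`drift_order`).

## ROI definition and vein exclusion

The localizer statistic is a one-sided paired *t* across runs of the
face-minus-object beta difference per voxel (the natural across-run test
when per-run betas are in hand; a GLM-contrast backend would be equivalent
in expectation). Voxels pass at uncorrected $p < 0.01$; the ROI is the
largest 4-connected (2-D) or 6-connected (3-D) component of passing voxels
within the anatomical search zone — face-touching connectivity being the
most conservative standard reading of "contiguous voxels". Size ties break
toward the component with the larger peak *t*, making the result
deterministic; no minimum cluster size is imposed. In the pipeline, the
localizer condition maps are first smoothed with a 2 mm FWHM Gaussian on
the patch (`localizer_fwhm_mm`), mirroring the convention that only
localizer data are smoothed; main-experiment patterns never are, since
fine-scale structure is the object of study.

Vein exclusion removes voxels whose face-condition PSC is **strictly
greater than 4%** — abnormally large signal changes at high field are the
signature of draining veins, not neural tissue. A voxel at exactly 4.0% is
retained; the tests pin this boundary. Degenerate localizer voxels
(zero-variance differences) can never enter an ROI: an identically zero
difference gets the identity convention $t = 0, p = 0.5$, and a constant
nonzero difference is flagged undefined.

## Pattern normalization and shared-pattern removal

Condition patterns are z-scored across voxels (mean 0, SD 1, $n-1$
convention) before contrasting, removing overall amplitude differences so
that contrasts reflect *spatial* bias. Division by the mean is available as
an alternative; both are sign-preserving affine maps, so the gradient
correlation is unaffected by the choice (asserted in the tests up to the
small mixing difference the two conventions induce on noisy data).

The response patterns of all conditions share a large common component —
the intrinsic sensitivity profile plus any vascular structure. To expose
part-specific spatial biases, `regress_out()` fits a simple OLS regression
(one regressor plus intercept, across voxels) of each part pattern on a
general pattern (whole-face or object responses) and keeps the residuals.
Simple rather than multiple regression is deliberate: the scientific claim
is about what survives removal of *one* shared profile. The pipeline
applies vein exclusion first, then normalization/regression, and records
the order in its manifest.

## Axis projection, profiles, and the gradient statistic

`project_to_axis()` computes, for each vertex, the nearest point on the
axis polyline (orthogonal foot within a segment or a segment endpoint): the
arc length of that point is the vertex's **position**, its distance the
off-axis offset. Points beyond either end clamp to the end — ROIs lie
alongside the drawn line in practice, but the behaviour must be defined —
and exact ties between equidistant segments resolve to the smaller arc
length. The projection is rigid-motion equivariant to 1e-9, verified
against a dense-sampling oracle.

Profiles (`build_profile()`) are fixed-width bins from position 0 with
per-bin mean, SEM and count; the default bin width is 1.2 mm (one voxel
pitch — published profiles of this kind state no bin width, and the
statistic below does not use bins). `gradient_correlation()` is computed at
the **vertex level** by default: it uses all the data and avoids binning
artifacts; the bin-level variant is available and agrees in sign on planted
gradients (asserted). Position is arc length in mm; for equally spaced bins
an ordinal index would give the identical Pearson r.

## Group inference and reliability

Per-subject correlations are tested against zero with a one-sample *t* on
the **raw** r values, two-sided, with Cohen's $d = \bar r / s_r$ — the raw-r
convention is what the standard $d$ = mean/sd effect-size report refers to.
Fisher-z is available (`transform = "fisher"`) and agrees in sign. No
correction across ROIs is applied by default (per-ROI tests are
conventionally reported uncorrected); a Bonferroni helper is provided.
Amplitude comparisons between conditions use two-sided paired *t* tests
across subjects.

Split-half reliability divides the 8 runs into odd and even halves,
averages the per-voxel eyes-minus-mouth difference within each half, and
correlates the two maps across voxels. Under the additive model (stable
per-voxel bias of variance $\sigma_s^2$ plus independent half-noise of
variance $\sigma_n^2$) the expected correlation is the attenuation ratio
$\sigma_s^2 / (\sigma_s^2 + \sigma_n^2)$; the test suite verifies this
within Monte-Carlo error at three planted ratios, with 500 voxels per
replicate so that the small-sample bias of the sample correlation is
negligible against the Monte-Carlo band.

## The CSS pRF control

A spatial gradient of face-part preference could in principle be a
retinotopic gradient in disguise. The control analysis fits each voxel's
population receptive field with the compressive spatial summation (CSS)
model: response $= g\,(\sum_{\text{pixels}} A_t \cdot G_{x,y,\sigma})^n$
convolved with the HRF, where $G$ is an isotropic 2-D Gaussian normalized
to unit sum over the pixel grid and $n$ is a static power-law exponent
($n<1$: compressive summation). Stimuli are the standard retinotopy
apertures: a 45 deg wedge revolving at 32 s/cycle (both directions) and
rings sweeping 28 s/cycle with 4 s rest (expanding and contracting), within
a 10 deg radius, binarised on a 64 x 64 pixel grid — coarse enough for desk
scale, fine enough that aperture quantization error is below 2% of disk
area. Runs are padded with 22 s blanks, which also isolates runs from HRF
leakage when several are concatenated for joint fitting.

Fitting is a coarse grid over centre, size and exponent
($x, y \in [-10, 10]$, $\sigma \in [0.1, 8]$ deg,
$n \in \{0.25, 0.5, 0.75, 1\}$ — conventional ranges for this model family,
treated as conventions rather than facts about any dataset) with gain and
offset solved by least squares at each candidate, followed by bounded
L-BFGS-B refinement from the top three grid candidates. Multi-start matters:
the $\sigma$–$n$ trade-off creates local optima that a single start can
fall into. $R^2$ is computed against the mean-only model and reported in
percent; fits at or below 2% are excluded (strictly-greater inclusion,
boundary pinned by tests). A flat series returns gain 0, $R^2$ 0 rather
than an error.

The negative control plants receptive fields with *no* spatial organization
across the patch and asserts that the fitted x- and y-maps show no
significant position gradient at the group level — the pattern expected if
face-part tuning, but not retinotopy, is spatially organised along the
axis.

## Numerical and design choices worth knowing

* **Degenerate inputs** error with typed conditions
  (`facegrad_zero_variance`, `facegrad_roi_not_found`,
  `facegrad_rank_error`, ...) rather than returning NaN; the two identity
  conventions ($t=0,p=0.5$ for a self-contrast; $t=0,p=1$ for identical
  paired columns) are documented exceptions.
* **Wedge apertures are computed in degrees** with the frame index reduced
  modulo the cycle: wedge boundaries for a 45 deg span are then exactly
  representable, making frames bit-identical across cycles and between
  cw/ccw time reversals. In radians, 1-ulp drift flipped pixels lying
  exactly on the diagonal boundaries.
* **Seeded determinism** throughout: every stochastic function takes a
  seed, and the pipeline derives per-subject and per-run seeds from the
  base seed, so a report is a pure function of its configuration.
* **Problem sizes** used in the validation suite are desk-scale choices:
  12 x 12 patches, 6-subject groups, 50 group replicates for recovery, 2000
  null simulations for calibration, 100 synthetic pRF voxels, 500-replicate
  attenuation checks. They give Monte-Carlo bands comfortably tighter than
  the properties being asserted.
* The eyes/mouth gradient magnitude at which recovery is validated is
  expressed as a signal-to-noise ratio: the across-voxel SD of the planted
  difference divided by the sampling SD of its 8-run-average GLM estimate
  (computed analytically from the design via `glm_beta_cov()`), so "SNR 1"
  means the planted effect exactly matches the estimator's own noise.

## Limitations

The patch is a flat sheet: cortical curvature, the volume-to-surface
projection, and the lateral-medial dimension (genuinely hard to reconstruct
within a sulcus) are out of scope, as is any automatic detection of the
anatomical landmark — the axis is user input. The simulation's noise model
is white by default; temporally structured noise inflates GLM variance in
ways `glm_beta_cov()` does not capture (use the AR(1) option to probe
this). Group inference is a one-sample *t* over subjects; hierarchical
models are out of scope.

## A worked run

```{r demo, eval = FALSE}
cfg <- pipeline_config(seed = 42)
rep <- run_pipeline(cfg)
rep$per_subject
tidy(rep$group)
cat(make_report(rep, plots = FALSE)$summary_text, sep = "\n")
```

On the default configuration this recovers strongly negative per-subject
gradient correlations (the planted eyes-posterior bias), a significant
negative group *t*, complete removal of the planted vein voxels, and
split-half reliabilities above 0.9.
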