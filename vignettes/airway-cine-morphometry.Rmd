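---
title: "Measuring dynamic upper-airway caliber from cine MRI"
author: "aircine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dynamic upper-airway caliber from cine MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aircine)
```

## The measurement problem

Sedatives relax upper-airway dilator muscles, and the clinically relevant
question is whether a drug combination narrows a child's pharyngeal airway.
Cine MRI answers it dynamically: a single axial slice — at the nasopharynx
(NP, the narrowest level) or the retroglossal airway (RG, the level most
affected by dilator tone) — is imaged repeatedly at 2–3 frames/s for roughly
72 frames while the subject breathes spontaneously. The airway lumen appears
as a dark region against brighter tissue. From each frame we extract three
outcome measures: the lumen cross-sectional area (mm²) and its
anterior–posterior (AP, image rows) and transverse (TX, image columns)
diameters (mm).

`aircine` implements the complete workflow: semi-automatic segmentation of
the lumen in every frame from a single user seed, conversion of masks to
physical measures, respiratory-cycle summarization, and the repeated-measures
statistics used to compare anesthetic conditions — plus a synthetic phantom
generator that provides analytic ground truth for validating all of it.

## Segmentation model and assumptions

Segmentation assumes a *dark lumen on brighter tissue* in each 2-D frame and
proceeds in three steps per frame:

1. **Profile bounds.** The 1-D intensity profiles through the seed along the
   image rows (AP) and columns (TX) are smoothed with a short moving average
   (default 3 px). Walking outward from the seed on each side, the first
   local maximum that marks a *significant dark-to-bright transition*
   becomes the rectangular limit on that side. "Significant" means the peak
   rises at least `min_prominence` (default 10% of the frame's intensity
   range) above the lowest profile value between it and the seed, and the
   peak value lies in the upper half of the profile's range — i.e., it is
   tissue-bright, not a dim wiggle on the edge slope. We deliberately do
   *not* use standard topographic prominence here: on noisy but flat tissue
   the next noise bump caps the topographic prominence of the true flank
   peak at roughly the noise amplitude, so genuine boundaries would be
   rejected whenever tissue texture is present. The seed-relative rise is
   also what "pixel values change significantly from the black airway to
   gray tissue" describes. A side with no qualifying peak falls back to the
   image border. A bright plateau adjacent to the well counts as a peak,
   with the limit placed at the plateau edge nearest the seed (a
   deterministic tie-break).
2. **Threshold.** Otsu's bimodal split of the intensities inside the
   rectangle. If the in-bounds histogram is effectively unimodal (one class
   nearly empty, or class means closer than twice the pooled within-class
   SD), the threshold falls back to the midpoint between the mean of the
   3×3 seed neighborhood and the mean of the boundary-peak pixels. A
   constant region raises a "no contrast" error.
3. **Region growing.** The 4-connected component of sub-threshold pixels
   containing the seed, completed by every sub-threshold pixel inside the
   component's bounding rows/columns — our reading of "all low-intensity
   pixels within the rectangular limits". The alternative reading (label
   every sub-threshold pixel in the profile rectangle regardless of
   connectivity) is available as `fill = "all"`. 4-connectivity is the
   conservative choice against diagonal leakage through thin bright septa.

For frames after the first, the seed is the rounded centroid of the previous
non-empty mask, falling back to the original user seed when the previous
mask was empty or the propagated seed no longer lies in lumen. Bounds and
(in auto mode) the threshold are recomputed every frame, which makes the
tracking robust to intensity drift. Because an off-center seed samples a
short chord — and short-chord bounds clip the lumen — each frame's
bounds→threshold→grow step is iterated to self-consistency: if the grown
mask's centroid lies more than one pixel from the seed, the step is redone
from the centroid, up to three times. The iteration is deterministic and a
centered seed is its fixed point.

A seed is rejected ("seed not in lumen") when its intensity falls in the
upper half of its own profiles' range; a zero-contrast frame instead passes
through to the border fallback, so a uniformly dark frame is still
segmentable. An empty mask (airway closure) is recorded as area 0 and
diameters 0 rather than dropped — dropping closed frames would bias the
minimum upward. If more than half the frames of a sequence come out empty a
warning is issued and processing continues, since airway closure is a
legitimate observation.

## Physical measures

Area is the lumen pixel count times the pixel area. Diameters are
bounding-box extents with the +1 pixel-center-to-edge convention (a one-pixel
mask has diameter one pixel width, not zero): AP uses the row spacing, TX the
column spacing, so anisotropic acquisitions are handled. With 0.5 mm pixels,
the convenient equivalence "2 pixels = 1 mm" holds.

## Respiratory-cycle summary

Each per-frame series is reduced to a "true" minimum (the average of all
breath valleys), a mean (the average of all frames) and a "true" maximum
(the average of all breath peaks). Extrema are local extrema of the raw
series with topographic prominence at least 10% of the series range
(breathing cycles are oscillations on a trace, so topographic prominence is
the right notion here, unlike in the profile-bounds step). Endpoints are
excluded because truncated first/last breaths would bias the averages; when
no qualifying interior extremum exists on a side, the single global
extremum is used, which also guarantees `t_min ≤ t_mean ≤ t_max` for
monotone and constant series. Zero-valued (closed-airway) frames are valid
valley candidates. No smoothing is applied by default — the extrema in the
workflow this reproduces are read off the raw trace — but a moving-average
window is exposed.

## Statistics

The statistics stage consumes only a long cohort table (subject, plane,
condition, measure, value, age) and is fully decoupled from imaging.

* `pairedCompare()` — baseline vs follow-up paired differences. The
  Shapiro–Wilk test at α = 0.05 gates between the paired t-test (t-based
  95% CI) and the Wilcoxon signed-rank test (Hodges–Lehmann pseudomedian
  CI); the workflow this reproduces states only "as appropriate", so the
  gate is explicit and documented. Cohen's d (paired) is mean(diff)/sd(diff);
  percent change is the mean of per-subject percent changes — not the ratio
  of means — because per-subject ratios respect the pairing. Subjects with a
  zero baseline are excluded from percent change with a warning.
* `fitLmm()` — dose–response: `change-from-baseline ~ time + age + baseline
  + (1 | subject)`, REML, Satterthwaite degrees of freedom, least-squares
  means of the change per time level with 95% CIs. A singular or failed
  random-intercept fit downgrades to a fixed-effects model with a flag.
* `multiplicityAdjust()` — Bonferroni by default, Holm available. The
  method is the caller's choice because the original analysis names none;
  Bonferroni is the transparent default and the conclusions at stake are
  insensitive to the choice (e.g. a raw p of 0.0184 in a 24-measure family
  is non-significant under either).
* `dunnettCompare()` — many-to-one comparisons of each time level against
  baseline for paired data (used for hemodynamic-style families). Per level
  the statistic is the paired t statistic; the family-wise adjustment is
  exact: central multivariate t with n−1 degrees of freedom and the
  empirical correlation matrix of the per-subject difference vectors. The
  integral uses a quasi-Monte-Carlo algorithm under a pinned internal RNG
  state (tolerance 10⁻⁴), so repeated calls give identical p-values and the
  caller's random stream is untouched.
* `pairedTPower()` / `solveSampleSize()` — exact noncentral-t power for the
  two-sided paired t-test. The α argument is the *post-adjustment*
  per-comparison level: a design with two primary outcomes at overall 0.05
  uses α = 0.025, where 22 pairs give 80% power at effect size d = 0.7.

## The synthetic phantom: what it emulates, what it does not

`phantomSpec()` describes a dark elliptical lumen (default intensity 20) on
brighter tissue (150, on an 8-bit-like scale) whose semi-axes oscillate
sinusoidally: `a(t) = a₀(1 + m·sin(2πt/T))`. Defaults are chosen as
plausible pediatric values and are configuration, not claims: 72 frames at
350 ms (the midpoint of a 300–400 ms acquisition interval), 0.5 mm isotropic
pixels on a 128×128 grid, semi-axes 4 mm (AP) × 6 mm (TX) giving a mean area
near 75 mm², a 3 s respiratory period (2–5 s is the plausible pediatric
range), 20% modulation, Gaussian noise SD 10 and 0.5 px PSF blur. An
optional per-cycle lognormal amplitude drift (`drift_sd`) emulates
breath-to-breath variability seen in real traces. Ground truth is analytic:
area π·a(t)·b(t), diameters 2a(t), 2b(t), with the per-sequence min/mean/max
taken over the sampled frames.

`cohortSpec()`/`makeCohort()` lay out the repeated-measures study: 22
subjects × 2 planes × 4 conditions (baseline "00" and 5/10/15 min), ages
uniform on 1–13 years, a per-subject normal semi-axis offset (SD 0.75 mm)
shared by both axes, and per-condition multiplicative effects with the
baseline fixed at exactly 1. The default effects are null — the design's
no-effect case. `makeCohort(images = FALSE)` skips rasterization and returns
the analytic ground-truth table directly; because a table with zero noise
would make every statistical simulation degenerate, that path accepts a
`measurement_cv` (lognormal measurement noise, default 5% in our
simulations, matched to the phantom segmentation error scale).

The phantom deliberately omits MR physics: no k-space sampling, no Rician
noise floor, no bias field, no motion artifacts beyond lumen-size
modulation, and the lumen is a convex ellipse while real airway sections are
crescent-shaped at some levels. Passing the recovery suite therefore
demonstrates that the algorithm is correct and accurate *under its stated
assumptions* (dark convex lumen, additive Gaussian noise, modest blur) — it
does not certify accuracy on pathological anatomies or artifact-laden
acquisitions.

## Validation results computed by this package

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **Segmentation accuracy** on 50 phantom sequences (72 frames each,
  semi-axes 3–6 mm, modulation 0.1–0.3, noise SD 5–15, blur 0.3–1 px):
  mean absolute diameter error ≤ 2 pixels and mean absolute relative area
  error ≤ 10% — the accuracy envelope quoted for this class of
  semi-automatic segmentation. Measured values are typically ≈ 0.5 px and
  ≈ 1–2%.
* **Oracle equivalence**: the region grower is pixel-exact against a
  brute-force flood fill on random noiseless fixtures.
* **Temporal closed form**: a 5-cycle sinusoid (offset 100, amplitude 20)
  summarizes to (80, 100, 120) within 2%.
* **Statistical calibration**: paired-test type-I error at nominal α;
  noncentral-t power matching Monte-Carlo simulation; mixed-model sign
  recovery of a −10% condition effect in ≥95% of 200 cohorts and null-cohort
  CI coverage near nominal; Dunnett family-wise error within Monte-Carlo
  tolerance of 0.05.
* **Determinism**: identical config and seed reproduce byte-identical
  pipeline outputs on the full default cohort.

## Numerical choices and tie-breaks

* Internal geometry is 1-based (row, col) pixel indexing throughout — the R
  convention shared by every imaging package this builds on; the CSV `frame`
  column is likewise 1-based with `time_ms = (frame − 1) × interval`.
* Ties among equally distant candidate peaks cannot arise within one side
  of a profile; plateau peaks resolve to the edge nearest the seed.
* Degenerate inputs are mapped to defined results rather than errors where
  a scientific reading exists: empty masks → zero metrics; constant series
  → (c, c, c) summaries; zero-extent bounds → empty mask; constant paired
  differences → a deterministic-shift result (p = 0, infinite d) or the
  all-zero result (p = 1, d = 0).
* The simulation problem sizes in the validation suite (50 phantom
  sequences; 2000 replicates for test calibration; 200 cohorts for the
  mixed model) were chosen so each check's Monte-Carlo error is well below
  the tolerance it asserts.

## Known limitations

* DICOM series are not read directly; convert to NIfTI (e.g. `dcm2niix`)
  first. NIfTI and multi-page TIFF (+ JSON sidecar) round-trip losslessly.
* The segmentation assumes one connected dark lumen; bifurcated or
  artifact-split lumens will be truncated to the seeded component (by
  design — the `fill = "all"` flag trades this for leakage risk).
* Least-squares-mean CIs from the degenerate (zero-residual) fit are
  unbounded; estimates remain exact.
* The stats stage tests differences; it does not perform equivalence (TOST)
  testing. Confidence intervals are reported so users can judge practical
  equivalence against their own margin; the package does not invent one.
* On the default synthetic cohort the breathing modulation is a pure
  sinusoid with identical phase in every condition, and the segmentation is
  robust enough that typical noise realizations never flip a mask pixel.
  A null cohort's measured between-condition differences can therefore be
  *exactly* zero, which the paired tests report as p = 1 and the mixed
  models as degenerate (NA) cells — an honest, if extreme, no-effect
  outcome. Real repeated acquisitions differ breath to breath; set
  `drift_sd > 0` (per-cycle lognormal amplitude drift) to emulate that
  variability when non-degenerate null statistics are wanted.
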