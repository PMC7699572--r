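# aircine

Dynamic upper-airway morphometry from cine MRI.

Sedatives and anesthetics relax the pharyngeal dilator muscles, and the
clinically relevant question in pediatric sedation is whether a drug
regimen narrows the child's airway. Cine MRI of a single axial slice —
nasopharyngeal (NP) or retroglossal (RG) — captures the airway lumen as a
dark region on brighter tissue, 2–3 frames per second over ~72 frames of
spontaneous breathing. `aircine` turns such sequences into airway outcome
measures and runs the repeated-measures comparisons used to contrast
anesthetic conditions:

1. **Segmentation** — from a single user seed on frame 1: 1-D intensity
   profiles through the seed along the anterior–posterior (AP = image rows)
   and transverse (TX = image columns) axes are scanned for the local peaks
   where pixel values change significantly from the black airway to gray
   tissue; these peaks delimit a rectangle, an Otsu threshold splits lumen
   from tissue inside it, and a 4-connected region grower labels the lumen.
   The seed propagates to later frames via the previous mask's centroid.
2. **Metrics** — per frame: cross-sectional area
   `A = N_pixels · s_row · s_col` (mm²) and diameters
   `AP = (row extent) · s_row`, `TX = (col extent) · s_col` (mm).
3. **Temporal summary** — per sequence, each measure reduces to a "true"
   minimum (mean over breath valleys), mean (over all frames) and maximum
   (mean over breath peaks), detected by prominence-gated local extrema.
4. **Statistics** — paired baseline-vs-follow-up tests (paired *t* or
   Wilcoxon, gated by Shapiro–Wilk) with Cohen's *d*
   (`d = mean(Δ)/sd(Δ)`) and per-subject percent change; linear
   mixed-effects dose–response
   `Δᵢⱼ = β₀ + β_time[j] + β_age·ageᵢ + β_base·baseᵢ + uᵢ + εᵢⱼ` with
   least-squares means per time level; Bonferroni/Holm family adjustment;
   and exact Dunnett many-to-one comparisons against baseline via the
   multivariate-*t* distribution of the paired *t* statistics.
5. **Power** — exact noncentral-*t* power for the two-sided paired *t*
   test: `power = P(|T′_{n−1, d√n}| > t_{1−α/2, n−1})`.

A synthetic breathing-phantom generator (elliptical lumen, sinusoidal size
modulation, Gaussian noise, PSF blur, per-subject and per-condition effects)
provides analytic ground truth for validating every stage.

## Worked example

```r
library(aircine)

## a breathing phantom: 4x6 mm semi-axes, 20% modulation, noise sd 10
ph <- makePhantomSequence(phantomSpec(seed = 5))
ph$sequence
#> CineSequence "phantom-seed5"
#>   128 x 128 pixels, 72 frames
#>   pixel spacing: 0.5 x 0.5 mm;  frame interval: 350 ms

masks <- segmentSequence(ph$sequence, seed = c(64, 64))
mets  <- sequenceMetrics(masks, ph$sequence)
head(mets, 3)
#>   frame time_ms area_mm2 ap_mm tx_mm
#> 1     1       0       76     8    12
#> 2     2     350       98     9    14
#> 3     3     700      109    10    14

summarizeTemporal(mets)
#>   measure t_min   t_mean  t_max n_peaks n_valleys
#> 1    area    48 77.59722 108.25       8         8
#> 2      ap     6  8.00000  10.00       8         8
#> 3      tx    10 12.04167  14.00       8         8
```

The phantom breathes with a 3 s period sampled at 350 ms, so ~8 respiratory
cycles fit in the 72-frame window: `n_peaks` finds them, and the measured
mean area (77.6 mm²) matches the analytic time-average of 77.8 mm². Against
ground truth, the mean diameter error on this sequence is 0.56 pixels and
the mean area error 1.0%.

The paired *t* power that sized this kind of study:

```r
pairedTPower(n = 22, d = 0.7, alpha = 0.025)
#> [1] 0.8002372
solveSampleSize(target = 0.8, d = 0.7, alpha = 0.025)
#> [1] 22
```

An end-to-end synthetic study (simulate → segment → summarize → stats)
with file-based stage handoff and provenance:

```r
runPipeline(list(seed = 11L,
                 simulate = list(n_subjects = 6L, n_frames = 24L,
                                 image_shape = c(64L, 64L))),
            out_dir = "run1")
## run1/ contains sequences/*.nii, segmentation/*_mask.nii + *_metrics.csv,
## cohort_measured.csv, paired_results.csv, lmm_results.csv, provenance.json
```

A thin CLI over the same functions lives at `inst/scripts/aircine.R`
(subcommands `run`, `simulate`, `segment`, `summarize`, `stats`, `power`).

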