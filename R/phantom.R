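#' Specify a breathing airway phantom
#'
#' Describes a synthetic axial cine sequence: a dark elliptical lumen on
#' brighter, noisy "tissue", whose semi-axes oscillate sinusoidally with the
#' respiratory cycle. The instantaneous AP semi-axis is
#' `a(t) = ap_semiaxis * (1 + modulation_fraction * sin(2*pi*t*frame_interval
#' / respiratory_period))` (likewise TX), so ground-truth area is
#' `pi * a(t) * b(t)` and diameters are `2*a(t)`, `2*b(t)`.
#'
#' Defaults emulate a pediatric upper-airway acquisition: 72 frames at 350 ms
#' (about 3 frames/s), 0.5 mm isotropic pixels, a ~3 s respiratory period,
#' and an 8-bit-like intensity scale with a dark lumen (20) against gray
#' tissue (150).
#'
#' @param image_shape integer(2), rows x cols in pixels.
#' @param pixel_spacing mm/pixel along (row, col); scalar recycled.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval ms between frames.
#' @param lumen_center (row, col) of the ellipse center in pixels (1-based;
#'   may be fractional).
#' @param ap_semiaxis,tx_semiaxis baseline lumen semi-axes in mm along the
#'   row (AP) and column (TX) directions.
#' @param modulation_fraction relative peak-to-mean size oscillation,
#'   in [0, 1).
#' @param respiratory_period ms per breathing cycle.
#' @param lumen_intensity,tissue_intensity grayscale means; lumen must be
#'   darker than tissue.
#' @param noise_sd additive Gaussian noise SD (grayscale units).
#' @param psf_sigma Gaussian blur SD in pixels (0 = no blur).
#' @param drift_sd cycle-amplitude drift SD as a fraction of
#'   `modulation_fraction` (0 = pure sinusoid); emulates breath-to-breath
#'   variability.
#' @param seed RNG seed for noise (and drift).
#' @return A `PhantomSpec` (classed list).
#' @examples
#' spec <- phantomSpec(n_frames = 12, noise_sd = 0)
#' seq <- makePhantomSequence(spec)$sequence
#' nFrames(seq)
#' @export
phantomSpec <- function(image_shape = c(128L, 128L),
                        pixel_spacing = 0.5,
                        n_frames = 72L,
                        frame_interval = 350,
                        lumen_center = (image_shape + 1) / 2,
                        ap_semiaxis = 4,
                        tx_semiaxis = 6,
                        modulation_fraction = 0.2,
                        respiratory_period = 3000,
                        lumen_intensity = 20,
                        tissue_intensity = 150,
                        noise_sd = 10,
                        psf_sigma = 0.5,
                        drift_sd = 0,
                        seed = 1L) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  spec <- list(
    image_shape = as.integer(image_shape),
    pixel_spacing = as.numeric(pixel_spacing),
    n_frames = as.integer(n_frames),
    frame_interval = as.numeric(frame_interval),
    lumen_center = as.numeric(lumen_center),
    ap_semiaxis = ap_semiaxis, tx_semiaxis = tx_semiaxis,
    modulation_fraction = modulation_fraction,
    respiratory_period = respiratory_period,
    lumen_intensity = lumen_intensity,
    tissue_intensity = tissue_intensity,
    noise_sd = noise_sd, psf_sigma = psf_sigma,
    drift_sd = drift_sd,
    seed = as.integer(seed)
  )
  if (spec$lumen_intensity >= spec$tissue_intensity)
    stop("lumen_intensity must be below tissue_intensity")
  if (spec$ap_semiaxis <= 0 || spec$tx_semiaxis <= 0)
    stop("semi-axes must be positive")
  if (spec$modulation_fraction < 0 || spec$modulation_fraction >= 1)
    stop("modulation_fraction must be in [0, 1)")
  if (spec$n_frames < 2L) stop("n_frames must be >= 2")
  if (any(spec$pixel_spacing <= 0)) stop("pixel_spacing must be positive")
  class(spec) <- c("PhantomSpec", "list")
  spec
}

## Per-frame modulation factors (one per frame). With drift, each breathing
## cycle's amplitude is scaled by a lognormal-ish factor, reproducible from
## the spec seed but independent of the per-frame noise stream.
phantomModulation <- function(spec) {
  t_ms <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  phase <- 2 * pi * t_ms / spec$respiratory_period
  amp <- rep(spec$modulation_fraction, spec$n_frames)
  if (spec$drift_sd > 0) {
    cycle <- floor(t_ms / spec$respiratory_period)
    set.seed(spec$seed + 77003L)
    fac <- exp(rnorm(max(cycle) + 1L, 0, spec$drift_sd))
    amp <- amp * fac[cycle + 1L]
  }
  1 + amp * sin(phase)
}

## Analytic ground truth for one frame given its modulation factor.
phantomTruthRow <- function(spec, t, mod) {
  a <- spec$ap_semiaxis * mod
  b <- spec$tx_semiaxis * mod
  data.frame(frame = t, area_mm2 = pi * a * b,
             ap_mm = 2 * a, tx_mm = 2 * b)
}

#' Rasterize one phantom frame
#'
#' @param spec a [phantomSpec()].
#' @param t frame index, 1-based (frame 1 is time 0).
#' @param noise optional pre-drawn noise matrix (used internally so the whole
#'   sequence shares one RNG stream); by default noise is drawn from
#'   `spec$seed + t`.
#' @return list with `frame` (numeric matrix, grayscale clamped to [0, 255])
#'   and `truth` (one-row data.frame: frame, area_mm2, ap_mm, tx_mm).
#' @examples
#' f <- makePhantomFrame(phantomSpec(noise_sd = 0, psf_sigma = 0), 1)
#' f$truth
#' @export
makePhantomFrame <- function(spec, t, noise = NULL) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (t < 1L || t > spec$n_frames)
    stop("frame index ", t, " outside 1..", spec$n_frames)
  mod <- phantomModulation(spec)[t]
  a_px <- spec$ap_semiaxis * mod / spec$pixel_spacing[1L]
  b_px <- spec$tx_semiaxis * mod / spec$pixel_spacing[2L]
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  ctr <- spec$lumen_center
  if (ctr[1L] - a_px < 1 || ctr[1L] + a_px > nr ||
      ctr[2L] - b_px < 1 || ctr[2L] + b_px > nc)
    stop("lumen ellipse extends beyond image bounds at frame ", t)
  dr <- (seq_len(nr) - ctr[1L]) / a_px
  dc <- (seq_len(nc) - ctr[2L]) / b_px
  inside <- outer(dr^2, dc^2, "+") <= 1
  img <- matrix(spec$tissue_intensity, nr, nc)
  img[inside] <- spec$lumen_intensity
  if (spec$psf_sigma > 0) {
    ## blur only a crop around the ellipse: everything beyond it is constant
    ## tissue, so the result is identical to blurring the full frame as long
    ## as the margin covers the kernel radius
    margin <- 2L * ceiling(3 * spec$psf_sigma) + 2L
    r1 <- max(1L, floor(ctr[1L] - a_px) - margin)
    r2 <- min(nr, ceiling(ctr[1L] + a_px) + margin)
    c1 <- max(1L, floor(ctr[2L] - b_px) - margin)
    c2 <- min(nc, ceiling(ctr[2L] + b_px) + margin)
    img[r1:r2, c1:c2] <- as.matrix(
      EBImage::gblur(EBImage::Image(img[r1:r2, c1:c2]),
                     sigma = spec$psf_sigma))
  }
  if (spec$noise_sd > 0) {
    if (is.null(noise)) {
      set.seed(spec$seed + t)
      noise <- matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), 255)
  list(frame = img, truth = phantomTruthRow(spec, t, mod))
}

#' Generate a full phantom cine sequence with analytic ground truth
#'
#' @param spec a [phantomSpec()].
#' @return list with `sequence` (a [CineSequence-class]), `truth` (per-frame
#'   data.frame: frame, area_mm2, ap_mm, tx_mm) and `summary` (data.frame
#'   measure, t_min, t_mean, t_max over the analytic per-frame values).
#' @details Output is fully reproducible from `spec$seed`. The ground-truth
#'   summary takes min/mean/max over the sampled frames (not the continuous
#'   envelope), matching what any frame-wise analysis can observe.
#' @examples
#' ph <- makePhantomSequence(phantomSpec(n_frames = 8, noise_sd = 0))
#' ph$summary
#' @export
makePhantomSequence <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  set.seed(spec$seed)
  arr <- array(0, c(nr, nc, spec$n_frames))
  truth <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    noise <- if (spec$noise_sd > 0)
      matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc) else NULL
    ft <- makePhantomFrame(spec, t, noise = noise)
    arr[, , t] <- ft$frame
    truth[[t]] <- ft$truth
  }
  truth <- do.call(rbind, truth)
  summ <- data.frame(
    measure = c("area", "ap", "tx"),
    t_min  = c(min(truth$area_mm2),  min(truth$ap_mm),  min(truth$tx_mm)),
    t_mean = c(mean(truth$area_mm2), mean(truth$ap_mm), mean(truth$tx_mm)),
    t_max  = c(max(truth$area_mm2),  max(truth$ap_mm),  max(truth$tx_mm))
  )
  seqobj <- cineSequence(arr, spec$pixel_spacing, spec$frame_interval,
                         identifier = sprintf("phantom-seed%d", spec$seed))
  list(sequence = seqobj, truth = truth, summary = summ)
}

#' Specify a synthetic study cohort
#'
#' Lays out a repeated-measures imaging study: each subject is imaged in each
#' plane under each condition. Condition "00" is the baseline and must have
#' multiplicative effect exactly 1; later conditions scale the subject's
#' lumen semi-axes. Subjects get a random baseline size offset (shared by
#' both semi-axes) and an age drawn uniformly from `age_range`.
#'
#' Defaults follow a 22-subject pediatric sedation study design: two planes
#' (nasopharyngeal NP, retroglossal RG), four conditions (baseline 00 and 5,
#' 10, 15 min after a drug change), ages 1-13 years, and null condition
#' effects (the no-effect case the study design must be able to detect
#' departures from).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param conditions ordered condition labels; first is baseline.
#' @param planes imaging plane labels.
#' @param condition_effects multiplicative semi-axis effect per condition;
#'   first element must be 1.
#' @param between_subject_sd SD (mm) of the per-subject baseline semi-axis
#'   offset.
#' @param age_range years, c(lo, hi).
#' @param seed RNG seed.
#' @return A `CohortSpec` (classed list).
#' @export
cohortSpec <- function(n_subjects = 22L,
                       conditions = c("00", "5", "10", "15"),
                       planes = c("NP", "RG"),
                       condition_effects = c(1, 1, 1, 1),
                       between_subject_sd = 0.75,
                       age_range = c(1, 13),
                       seed = 1L) {
  if (length(condition_effects) != length(conditions))
    stop("condition_effects must match conditions in length")
  if (condition_effects[1L] != 1)
    stop("the first (baseline) condition must have effect exactly 1")
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  spec <- list(n_subjects = as.integer(n_subjects),
               conditions = as.character(conditions),
               planes = as.character(planes),
               condition_effects = as.numeric(condition_effects),
               between_subject_sd = between_subject_sd,
               age_range = as.numeric(age_range),
               seed = as.integer(seed))
  class(spec) <- c("CohortSpec", "list")
  spec
}

#' Generate a synthetic cohort of cine sequences with ground truth
#'
#' One sequence per (subject, plane, condition). Each subject's baseline
#' semi-axes are the base phantom's plus a normal offset
#' (`between_subject_sd`); each condition multiplies both semi-axes by its
#' effect. Everything is reproducible from `cohort$seed`.
#'
#' @param cohort a [cohortSpec()].
#' @param base a [phantomSpec()] providing image geometry, intensities,
#'   modulation, noise and blur.
#' @param images if `FALSE`, skip rasterization and return only the analytic
#'   ground-truth table (fast path for statistical simulation).
#' @param measurement_cv optional coefficient of variation of multiplicative
#'   measurement noise applied to the ground-truth summary values in the
#'   returned table (only meaningful with `images = FALSE`); emulates
#'   segmentation error so table-level simulations are not degenerate.
#' @return list with `truth` (a long cohort table: subject, plane, condition,
#'   measure, value, age — measure runs over area/ap/tx x min/mean/max, e.g.
#'   `"area_mean"`), `ages` (per-subject), and, when `images = TRUE`,
#'   `sequences` (named list of [CineSequence-class]) and `specs` (the
#'   per-cell PhantomSpec objects, carrying the per-sequence seeds).
#' @examples
#' cs <- cohortSpec(n_subjects = 3, seed = 9)
#' tab <- makeCohort(cs, phantomSpec(n_frames = 6), images = FALSE)$truth
#' head(tab)
#' @export
makeCohort <- function(cohort, base, images = TRUE, measurement_cv = 0) {
  stopifnot(inherits(cohort, "CohortSpec"), inherits(base, "PhantomSpec"))
  set.seed(cohort$seed)
  offs <- rnorm(cohort$n_subjects, 0, cohort$between_subject_sd)
  ages <- runif(cohort$n_subjects, cohort$age_range[1L], cohort$age_range[2L])
  ncell <- cohort$n_subjects * length(cohort$planes) * length(cohort$conditions)
  subseeds <- sample.int(.Machine$integer.max - 1000L, ncell)
  grid <- expand.grid(condition = cohort$conditions,
                      plane = cohort$planes,
                      subject = seq_len(cohort$n_subjects),
                      stringsAsFactors = FALSE)
  sequences <- if (images) vector("list", nrow(grid)) else NULL
  specs <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- grid$subject[i]; pl <- grid$plane[i]; cond <- grid$condition[i]
    eff <- cohort$condition_effects[match(cond, cohort$conditions)]
    sp <- base
    sp$ap_semiaxis <- max(0.5, (base$ap_semiaxis + offs[s]) * eff)
    sp$tx_semiaxis <- max(0.5, (base$tx_semiaxis + offs[s]) * eff)
    sp$seed <- subseeds[i]
    specs[[i]] <- sp
    id <- sprintf("S%02d_%s_%s", s, pl, cond)
    if (images) {
      ph <- makePhantomSequence(sp)
      ph$sequence@identifier <- id
      sequences[[i]] <- ph$sequence
      summ <- ph$summary
    } else {
      mod <- phantomModulation(sp)
      a <- sp$ap_semiaxis * mod; b <- sp$tx_semiaxis * mod
      vals <- list(area = pi * a * b, ap = 2 * a, tx = 2 * b)
      summ <- data.frame(
        measure = names(vals),
        t_min = vapply(vals, min, 0),
        t_mean = vapply(vals, mean, 0),
        t_max = vapply(vals, max, 0))
    }
    rows[[i]] <- data.frame(
      subject = sprintf("S%02d", s), plane = pl, condition = cond,
      measure = c(paste0(summ$measure, "_min"),
                  paste0(summ$measure, "_mean"),
                  paste0(summ$measure, "_max")),
      value = c(summ$t_min, summ$t_mean, summ$t_max),
      age = ages[s], row.names = NULL)
  }
  truth <- do.call(rbind, rows)
  if (measurement_cv > 0) {
    truth$value <- truth$value *
      exp(rnorm(nrow(truth), 0, measurement_cv))
  }
  out <- list(truth = truth, ages = ages)
  if (images) {
    names(sequences) <- vapply(sequences, identifier, "")
    out$sequences <- sequences
    out$specs <- specs
  }
  out
}
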