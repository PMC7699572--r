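## Segmentation of the airway lumen, frame by frame:
##   1. profileBounds(): 1-D intensity profiles through the seed along the AP
##      (row) and TX (column) axes; the nearest sufficiently prominent local
##      maximum on each side of the seed marks where the dark lumen gives way
##      to bright tissue -> rectangular search limits.
##   2. autoThreshold(): Otsu split of the in-bounds intensities.
##   3. regionGrow(): 4-connected component of sub-threshold pixels containing
##      the seed, completed by the sub-threshold pixels inside the component's
##      bounding box ("all low-intensity pixels within the rectangular
##      limits").
##   4. segmentSequence(): frame 1 from the user seed, later frames seeded at
##      the previous mask's centroid.

## Local-maximum runs of a 1-D profile with their topographic prominence.
## Plateaus are collapsed to runs (start..end). A boundary run qualifies when
## it exceeds its single inward neighbor (the profile "peaks into" the image
## border), so a bright plateau flanking a dark well is always a candidate.
## Prominence is the drop from the run value to the key saddle: on each side
## the walk continues through values <= v and records the minimum; the
## prominence is v minus the higher of the two side minima.
## Returns data.frame(start, end, value, prominence).
profilePeaks <- function(s) {
  empty <- list(start = integer(), end = integer(),
                value = numeric(), prominence = numeric())
  n <- length(s)
  if (n < 2L) return(empty)
  r <- rle(s)
  k <- length(r$values)
  if (k == 1L) return(empty)
  v <- r$values
  starts <- cumsum(c(1L, r$lengths[-k]))
  ends <- starts + r$lengths - 1L
  isMax <- c(TRUE, v[-1L] > v[-k]) & c(v[-k] > v[-1L], TRUE)
  which_max <- which(isMax)
  m <- length(which_max)
  if (!m) return(empty)
  prom <- numeric(m)
  for (i in seq_len(m)) {
    j <- which_max[i]
    lmin <- v[j]; jj <- j - 1L
    while (jj >= 1L && v[jj] <= v[j]) {
      if (v[jj] < lmin) lmin <- v[jj]
      jj <- jj - 1L
    }
    rmin <- v[j]; jj <- j + 1L
    while (jj <= k && v[jj] <= v[j]) {
      if (v[jj] < rmin) rmin <- v[jj]
      jj <- jj + 1L
    }
    ## a boundary run has no outer side; its prominence comes from the
    ## inward side alone
    side <- c(if (j > 1L) lmin, if (j < k) rmin)
    prom[i] <- v[j] - max(side)
  }
  list(start = starts[which_max], end = ends[which_max],
       value = v[which_max], prominence = prom)
}

movingAverage <- function(s, window) {
  if (window <= 1L) return(s)
  kern <- rep(1 / window, window)
  ## pad by edge replication so the profile keeps its length
  half <- (window - 1L) %/% 2L
  padded <- c(rep(s[1L], half), s, rep(s[length(s)], window - 1L - half))
  as.numeric(stats::filter(padded, kern, sides = 1L))[(window - 1L + 1L):(window - 1L + length(s))]
}

## Nearest qualifying peak run strictly below (side = -1) or above (side =
## +1) pos on profile s. Qualification is seed-relative: the run must rise by
## at least min_prom above the minimum of the profile between the seed and
## the run (the significance of the dark-to-bright transition), and its
## value must lie in the upper half of the profile's range (a lumen boundary
## is bright tissue, not a dim wiggle on the edge slope). For a plateau run
## the limit index is the run edge nearest the seed (deterministic
## tie-break). Returns c(index, prominence) or NULL.
nearestPeak <- function(peaks, s, pos, side, min_prom) {
  midrange <- mean(range(s))
  keep <- if (side < 0) peaks$end < pos else peaks$start > pos
  if (!any(keep)) return(NULL)
  edge <- if (side < 0) peaks$end[keep] else peaks$start[keep]
  value <- peaks$value[keep]
  ord <- order(abs(edge - pos))   # nearest first
  for (i in ord) {
    between <- s[min(edge[i], pos):max(edge[i], pos)]
    prom <- value[i] - min(between)
    if (prom >= min_prom && value[i] >= midrange)
      return(c(edge[i], prom))
  }
  NULL
}

#' Find rectangular airway limits from intensity profiles through the seed
#'
#' Extracts the 1-D intensity profile through the seed along each image axis,
#' smooths it with a moving average, and takes the nearest local maximum on
#' each side of the seed that marks a significant dark-to-bright transition —
#' the bright tissue flanking the dark lumen — as the rectangular limit on
#' that side. A peak qualifies when it rises by at least `min_prominence`
#' above the profile minimum between it and the seed and its value lies in
#' the upper half of the profile's range (tissue-bright, not a dim wiggle on
#' the edge slope). Sides with no qualifying peak fall back to the image
#' border.
#'
#' @param frame numeric matrix (grayscale).
#' @param seed c(row, col), 1-based, inside the frame.
#' @param smooth moving-average window in pixels (default 3).
#' @param min_prominence minimum peak prominence in grayscale units;
#'   `NULL` (default) uses 10% of the frame's intensity range.
#' @return A [ProfileBounds-class].
#' @details Errors with "seed not in lumen" when the seed intensity falls in
#'   the upper half of its own profiles' intensity range — a seed placed in
#'   bright tissue cannot delimit a dark lumen. A zero-contrast frame passes
#'   through to the border fallback instead.
#' @examples
#' img <- matrix(150, 9, 9); img[4:6, 3:7] <- 20
#' boundsRange(profileBounds(img, c(5, 5)))
#' @export
profileBounds <- function(frame, seed, smooth = 3L, min_prominence = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  r0 <- as.integer(round(seed[1L])); c0 <- as.integer(round(seed[2L]))
  if (r0 < 1L || r0 > nr || c0 < 1L || c0 > nc)
    stop("seed (", r0, ", ", c0, ") outside image bounds")
  if (is.null(min_prominence))
    min_prominence <- 0.1 * diff(range(frame))
  ap <- movingAverage(frame[, c0], smooth)   # profile along rows
  tx <- movingAverage(frame[r0, ], smooth)   # profile along cols
  prng <- range(c(ap, tx))
  ## a seed in the dark lumen sits in the lower half of its own profiles;
  ## a flat (zero-contrast) image cannot discriminate and is let through to
  ## the border fallback
  if (diff(prng) > 0 && frame[r0, c0] >= mean(prng))
    stop("seed not in lumen")
  apPeaks <- profilePeaks(ap)
  txPeaks <- profilePeaks(tx)
  side <- function(pk, prof, pos, dir) {
    p <- nearestPeak(pk, prof, pos, dir, min_prominence)
    if (is.null(p)) c(NA_real_, NA_real_) else p
  }
  rl <- side(apPeaks, ap, r0, -1L); rh <- side(apPeaks, ap, r0, +1L)
  cl <- side(txPeaks, tx, c0, -1L); ch <- side(txPeaks, tx, c0, +1L)
  new("ProfileBounds",
      rowLo = if (is.na(rl[1L])) 1L else as.integer(rl[1L]),
      rowHi = if (is.na(rh[1L])) nr else as.integer(rh[1L]),
      colLo = if (is.na(cl[1L])) 1L else as.integer(cl[1L]),
      colHi = if (is.na(ch[1L])) nc else as.integer(ch[1L]),
      prominences = c(rl[2L], rh[2L], cl[2L], ch[2L]))
}

#' Automatic lumen/tissue threshold within the profile bounds
#'
#' Otsu's bimodal split of the intensities inside the rectangular bounds.
#' When the in-bounds histogram is effectively unimodal (one Otsu class
#' nearly empty or class means separated by less than twice the pooled
#' within-class SD), falls back to the midpoint between the mean of the 3x3
#' seed neighborhood and the mean of the profile-peak (boundary) pixels.
#'
#' @param frame numeric matrix.
#' @param bounds a [ProfileBounds-class].
#' @param seed c(row, col); required only for the unimodal fallback.
#' @return Grayscale threshold (numeric scalar).
#' @export
autoThreshold <- function(frame, bounds, seed = NULL) {
  sub <- frame[bounds@rowLo:bounds@rowHi, bounds@colLo:bounds@colHi,
               drop = FALSE]
  rng <- range(sub)
  if (diff(rng) == 0) stop("no contrast within bounds")
  thr <- EBImage::otsu(EBImage::Image(sub), range = rng, levels = 256L)
  lowset <- sub <= thr
  pLow <- mean(lowset)
  muL <- mean(sub[lowset]); muH <- mean(sub[!lowset])
  sdPooled <- sqrt(mean(c(var(as.numeric(sub[lowset])),
                          var(as.numeric(sub[!lowset]))), na.rm = TRUE))
  unimodal <- pLow < 0.02 || pLow > 0.98 ||
    (is.finite(sdPooled) && (muH - muL) < 2 * sdPooled)
  if (unimodal && !is.null(seed)) {
    r0 <- round(seed[1L]); c0 <- round(seed[2L])
    nb <- frame[max(1, r0 - 1):min(nrow(frame), r0 + 1),
                max(1, c0 - 1):min(ncol(frame), c0 + 1)]
    edge <- c(frame[bounds@rowLo, c0], frame[bounds@rowHi, c0],
              frame[r0, bounds@colLo], frame[r0, bounds@colHi])
    thr <- (mean(nb) + mean(edge)) / 2
  }
  as.numeric(thr)
}

## 4-connected component of the candidate set containing the seed, via
## connected-component labeling on the (small) in-bounds crop.
floodFill4 <- function(candidate, seedRow, seedCol) {
  if (!candidate[seedRow, seedCol])
    return(matrix(FALSE, nrow(candidate), ncol(candidate)))
  lab <- matrix(as.numeric(EBImage::bwlabel(EBImage::Image(candidate * 1))),
                nrow(candidate), ncol(candidate))
  lab == lab[seedRow, seedCol]
}

#' Grow the airway region from a seed within rectangular bounds
#'
#' Takes the 4-connected component of sub-threshold (`intensity < threshold`)
#' pixels inside the bounds that contains the seed, then unions every
#' sub-threshold in-bounds pixel lying within that component's bounding
#' rows/columns — the "all low-intensity pixels within the rectangular
#' limits" completion. With `fill = "all"` every sub-threshold pixel inside
#' the profile bounds is labeled instead, regardless of connectivity.
#'
#' @param frame numeric matrix.
#' @param seed c(row, col), 1-based.
#' @param bounds a [ProfileBounds-class].
#' @param threshold grayscale threshold, strictly between typical lumen and
#'   tissue intensities.
#' @param fill `"connected"` (default; component + bounding-box completion)
#'   or `"all"` (every sub-threshold pixel in bounds).
#' @return An [AirwayMask-class]; empty (flagged) iff the seed pixel is at or
#'   above the threshold or the bounds are degenerate.
#' @examples
#' img <- matrix(200, 10, 10); img[4:6, 4:6] <- 10
#' b <- new("ProfileBounds", rowLo = 2L, rowHi = 9L, colLo = 2L, colHi = 9L,
#'          prominences = rep(NA_real_, 4))
#' sum(maskMatrix(regionGrow(img, c(5, 5), b, 100)))
#' @export
regionGrow <- function(frame, seed, bounds, threshold,
                       fill = c("connected", "all")) {
  fill <- match.arg(fill)
  r0 <- as.integer(round(seed[1L])); c0 <- as.integer(round(seed[2L]))
  emptyMask <- function() new("AirwayMask",
    mask = matrix(FALSE, nrow(frame), ncol(frame)),
    bounds = bounds, threshold = as.numeric(threshold), empty = TRUE)
  rl <- bounds@rowLo; rh <- bounds@rowHi
  cl <- bounds@colLo; ch <- bounds@colHi
  if (rh <= rl || ch <= cl) return(emptyMask())          # degenerate bounds
  if (r0 < rl || r0 > rh || c0 < cl || c0 > ch) return(emptyMask())
  if (frame[r0, c0] >= threshold) return(emptyMask())
  crop <- frame[rl:rh, cl:ch, drop = FALSE]
  cand <- crop < threshold
  if (fill == "all") {
    sel <- cand
  } else {
    comp <- floodFill4(cand, r0 - rl + 1L, c0 - cl + 1L)
    rr <- range(which(rowSums(comp) > 0))
    cc <- range(which(colSums(comp) > 0))
    sel <- comp
    boxed <- cand
    boxed[-(rr[1L]:rr[2L]), ] <- FALSE
    boxed[, -(cc[1L]:cc[2L])] <- FALSE
    sel <- sel | boxed
  }
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  mask[rl:rh, cl:ch] <- sel
  new("AirwayMask", mask = mask, bounds = bounds,
      threshold = as.numeric(threshold), empty = !any(mask))
}

#' Segmentation parameters
#'
#' @param threshold `"auto"` (per-frame Otsu via [autoThreshold()]) or a
#'   fixed grayscale value.
#' @param smooth profile moving-average window, pixels.
#' @param min_prominence minimum profile-peak prominence (grayscale); `NULL`
#'   = 10% of each frame's intensity range.
#' @param fill region completion rule, see [regionGrow()].
#' @return A named list of parameters for [segmentSequence()].
#' @export
segmentParams <- function(threshold = "auto", smooth = 3L,
                          min_prominence = NULL,
                          fill = c("connected", "all")) {
  list(threshold = threshold, smooth = as.integer(smooth),
       min_prominence = min_prominence, fill = match.arg(fill))
}

## Segment one frame from a seed; invalid seed (in tissue / out of lumen)
## yields NULL rather than an error. The bounds -> threshold -> grow step is
## iterated to self-consistency: if the grown mask's centroid moves away
## from the seed (an off-center seed samples a short chord, so its profile
## bounds clip the lumen) the step is redone from the centroid, up to
## `maxIter` times. Deterministic, and a fixed point under a centered seed.
segmentFrame <- function(frame, seed, params, maxIter = 3L) {
  once <- function(sd) {
    bounds <- tryCatch(
      profileBounds(frame, sd, smooth = params$smooth,
                    min_prominence = params$min_prominence),
      error = function(e) NULL)
    if (is.null(bounds)) return(NULL)
    thr <- if (identical(params$threshold, "auto"))
      tryCatch(autoThreshold(frame, bounds, seed = sd),
               error = function(e) NA_real_)
      else as.numeric(params$threshold)
    if (is.na(thr)) return(NULL)
    regionGrow(frame, sd, bounds, thr, fill = params$fill)
  }
  cur <- once(seed)
  if (is.null(cur) || isEmptyMask(cur)) return(cur)
  for (it in seq_len(maxIter - 1L)) {
    ctr <- maskCentroid(cur)
    if (max(abs(ctr - round(seed))) <= 1) break   # already centered
    nxt <- once(ctr)
    if (is.null(nxt) || isEmptyMask(nxt)) break
    seed <- ctr
    cur <- nxt
  }
  cur
}

maskCentroid <- function(mask) {
  w <- which(maskMatrix(mask), arr.ind = TRUE)
  c(round(mean(w[, 1L])), round(mean(w[, 2L])))
}

#' Segment every frame of a cine sequence from a single user seed
#'
#' Frame 1 is segmented from the user-provided seed; each subsequent frame is
#' seeded at the rounded centroid of the previous non-empty mask, falling
#' back to the original user seed when the previous mask was empty or the
#' propagated seed no longer lies in lumen. Rectangular bounds and (in auto
#' mode) the threshold are recomputed per frame, which makes the tracking
#' robust to intensity drift.
#'
#' @param seq a [CineSequence-class].
#' @param seed c(row, col) on frame 1, inside the lumen.
#' @param params a [segmentParams()] list.
#' @return List of [AirwayMask-class], one per frame, in temporal order.
#'   Errors if frame 1 yields an empty mask ("initial seed failed"); if more
#'   than half the masks come out empty a warning is issued and processing
#'   continues (a closing airway is a legitimate observation).
#' @examples
#' ph <- makePhantomSequence(phantomSpec(n_frames = 4, noise_sd = 5, seed = 2))
#' masks <- segmentSequence(ph$sequence, seed = c(64, 64))
#' sum(maskMatrix(masks[[1]]))
#' @export
segmentSequence <- function(seq, seed, params = segmentParams()) {
  stopifnot(is(seq, "CineSequence"))
  n <- nFrames(seq)
  masks <- vector("list", n)
  first <- segmentFrame(getFrame(seq, 1L), seed, params)
  if (is.null(first) || isEmptyMask(first))
    stop("initial seed failed: no lumen found at (",
         seed[1L], ", ", seed[2L], ") on frame 1 of ", identifier(seq))
  masks[[1L]] <- first
  for (i in seq_len(n)[-1L]) {
    frame <- getFrame(seq, i)
    prev <- masks[[i - 1L]]
    cur <- NULL
    if (!isEmptyMask(prev))
      cur <- segmentFrame(frame, maskCentroid(prev), params)
    if (is.null(cur) || isEmptyMask(cur)) {
      fb <- segmentFrame(frame, seed, params)          # original user seed
      if (!is.null(fb)) cur <- fb
    }
    if (is.null(cur))
      cur <- new("AirwayMask",
                 mask = matrix(FALSE, nrow(frame), ncol(frame)),
                 bounds = new("ProfileBounds", rowLo = 1L,
                              rowHi = nrow(frame), colLo = 1L,
                              colHi = ncol(frame),
                              prominences = rep(NA_real_, 4)),
                 threshold = NA_real_, empty = TRUE)
    masks[[i]] <- cur
  }
  nEmpty <- sum(vapply(masks, isEmptyMask, TRUE))
  if (nEmpty > n / 2)
    warning(nEmpty, "/", n, " frames of ", identifier(seq),
            " segmented empty (airway closure?)")
  masks
}
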