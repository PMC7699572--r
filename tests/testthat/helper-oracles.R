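## Independent oracles and fixture builders shared across tests. These stay
## deliberately naive: correctness by obviousness, not speed.

## Stack-based flood fill (4-connectivity) of sub-threshold pixels within a
## rectangle -- the brute-force oracle for regionGrow's connected component.
oracleFloodFill <- function(frame, seed, rect, threshold) {
  nr <- nrow(frame); nc <- ncol(frame)
  inRect <- function(r, c) r >= rect[1] && r <= rect[2] &&
    c >= rect[3] && c <= rect[4]
  visited <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  if (!inRect(seed[1], seed[2]) || frame[seed[1], seed[2]] >= threshold)
    return(out)
  stack <- list(seed)
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    r <- p[1]; c <- p[2]
    if (visited[r, c]) next
    visited[r, c] <- TRUE
    if (!inRect(r, c) || frame[r, c] >= threshold) next
    out[r, c] <- TRUE
    for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
      if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc &&
          !visited[d[1], d[2]])
        stack[[length(stack) + 1L]] <- d
  }
  out
}

## Apply regionGrow's completion rule to an oracle component: add every
## sub-threshold pixel in the rectangle lying within the component's
## bounding box.
oracleComplete <- function(frame, comp, rect, threshold) {
  if (!any(comp)) return(comp)
  rr <- range(which(rowSums(comp) > 0))
  cc <- range(which(colSums(comp) > 0))
  out <- comp
  for (r in max(rect[1], rr[1]):min(rect[2], rr[2]))
    for (c in max(rect[3], cc[1]):min(rect[4], cc[2]))
      if (frame[r, c] < threshold) out[r, c] <- TRUE
  out
}

## Count pixels whose center satisfies the ellipse inequality -- the
## rasterization oracle, written from the inequality directly.
oracleEllipseCount <- function(shape, center, a_px, b_px) {
  cnt <- 0L
  for (r in seq_len(shape[1]))
    for (c in seq_len(shape[2]))
      if (((r - center[1]) / a_px)^2 + ((c - center[2]) / b_px)^2 <= 1)
        cnt <- cnt + 1L
  cnt
}

## A quick low-noise phantom for tests that just need a segmentable sequence.
testPhantom <- function(n_frames = 6L, noise_sd = 5, psf_sigma = 0.5,
                        seed = 42L, ...) {
  makePhantomSequence(phantomSpec(n_frames = n_frames, noise_sd = noise_sd,
                                  psf_sigma = psf_sigma, seed = seed, ...))
}

pbRect <- function(b) { r <- boundsRange(b); c(r[1], r[2], r[3], r[4]) }

freeBounds <- function(nr, nc)
  new("ProfileBounds", rowLo = 1L, rowHi = as.integer(nr),
      colLo = 1L, colHi = as.integer(nc), prominences = rep(NA_real_, 4))
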