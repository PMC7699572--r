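#' Per-frame airway metrics in physical units
#'
#' Area is the lumen pixel count times the pixel area; the AP diameter is the
#' mask's row extent (max row - min row + 1, pixel-center-to-edge convention,
#' so a one-pixel mask has diameter one pixel width) times the row spacing,
#' and the TX diameter likewise over columns. An empty mask (closed airway)
#' contributes zeros rather than being dropped — dropping would bias minima
#' upward.
#'
#' @param mask an [AirwayMask-class].
#' @param pixel_spacing mm/pixel along (row, col).
#' @param frame 1-based frame index.
#' @param frame_interval ms between frames.
#' @return One-row data.frame: frame, time_ms, area_mm2, ap_mm, tx_mm.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
#' msk <- new("AirwayMask", mask = m,
#'            bounds = new("ProfileBounds", rowLo = 1L, rowHi = 8L,
#'                         colLo = 1L, colHi = 8L,
#'                         prominences = rep(NA_real_, 4)),
#'            threshold = 100, empty = FALSE)
#' frameMetrics(msk, c(0.5, 0.5), 1, 350)  # area 2.25 mm2, diameters 1.5 mm
#' @export
frameMetrics <- function(mask, pixel_spacing, frame, frame_interval) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  m <- maskMatrix(mask)
  if (!any(m)) {
    area <- ap <- tx <- 0
  } else {
    area <- sum(m) * pixel_spacing[1L] * pixel_spacing[2L]
    rows <- range(which(rowSums(m) > 0))
    cols <- range(which(colSums(m) > 0))
    ap <- (rows[2L] - rows[1L] + 1L) * pixel_spacing[1L]
    tx <- (cols[2L] - cols[1L] + 1L) * pixel_spacing[2L]
  }
  data.frame(frame = as.integer(frame),
             time_ms = (as.integer(frame) - 1L) * frame_interval,
             area_mm2 = area, ap_mm = ap, tx_mm = tx)
}

#' Metrics table for a whole sequence
#'
#' @param masks list of [AirwayMask-class], one per frame (temporal order).
#' @param seq the [CineSequence-class] the masks came from (supplies pixel
#'   spacing, frame interval and frame count).
#' @return data.frame with one row per frame and the fixed columns
#'   `frame,time_ms,area_mm2,ap_mm,tx_mm`; frame 1 is time 0.
#' @examples
#' ph <- makePhantomSequence(phantomSpec(n_frames = 4, noise_sd = 5, seed = 3))
#' masks <- segmentSequence(ph$sequence, c(64, 64))
#' sequenceMetrics(masks, ph$sequence)
#' @export
sequenceMetrics <- function(masks, seq) {
  stopifnot(is(seq, "CineSequence"))
  if (length(masks) != nFrames(seq))
    stop("got ", length(masks), " masks for ", nFrames(seq), " frames")
  rows <- lapply(seq_along(masks), function(i)
    frameMetrics(masks[[i]], pixelSpacing(seq), i, frameInterval(seq)))
  do.call(rbind, rows)
}
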