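## Sidecar convention: "<image>.json" next to the image file holds
## pixel_spacing (mm, length 2), frame_interval_ms, and identifier. NIfTI
## carries spacing/timing in pixdim as well (pixdim[1:2] = mm, pixdim[3] =
## frame interval in ms for these single-slice-over-time stacks); the sidecar
## wins when both are present. TIFF carries no physical metadata, so the
## sidecar is mandatory there.

sidecarPath <- function(path) {
  base <- sub("\\.nii(\\.gz)?$|\\.tiff?$", "", path, ignore.case = TRUE)
  paste0(base, ".json")
}

readSidecar <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

writeSidecar <- function(path, seq) {
  jsonlite::write_json(
    list(pixel_spacing = pixelSpacing(seq),
         frame_interval_ms = frameInterval(seq),
         identifier = identifier(seq)),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
}

#' Read a cine sequence from disk
#'
#' Supported containers: NIfTI-1 (`.nii` / `.nii.gz`, rows x cols x frames)
#' and multi-page TIFF (`.tif` / `.tiff`, stored on a [0, 1] scale and
#' rescaled to 0-255 on read). A JSON sidecar (`<image>.json`) supplies pixel
#' spacing (mm) and frame interval (ms); for NIfTI the header `pixdim` is the
#' fallback. DICOM series are not supported; convert to NIfTI first.
#'
#' @param path image file path.
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff"`.
#' @param pixel_spacing,frame_interval optional overrides; used when the
#'   container and sidecar carry no metadata.
#' @return A [CineSequence-class].
#' @seealso [writeSequence()]
#' @export
readSequence <- function(path, format = c("auto", "nifti", "tiff"),
                         pixel_spacing = NULL, frame_interval = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
      else if (dir.exists(path) || grepl("\\.dcm$", path, ignore.case = TRUE))
        stop("DICOM input is not supported; convert the series to NIfTI ",
             "(e.g. with dcm2niix) and retry")
      else stop("unrecognized sequence format: ", path)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- readSidecar(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    if (length(dim(arr)) != 3L)
      stop("expected a rows x cols x frames NIfTI, got ",
           length(dim(arr)), " dimensions")
    pd <- RNifti::pixdim(img)
    spacing <- pixel_spacing %||% sc$pixel_spacing %||% pd[1:2]
    interval <- frame_interval %||% sc$frame_interval_ms %||%
      (if (length(pd) >= 3L && pd[3L] > 0) pd[3L] else NULL)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    shapes <- unique(vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), ""))
    if (length(shapes) > 1L)
      stop("mixed frame shapes in TIFF: ", paste(shapes, collapse = ", "))
    arr <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
    for (i in seq_along(pages)) {
      p <- pages[[i]]
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale channels
      arr[, , i] <- p * 255
    }
    spacing <- pixel_spacing %||% sc$pixel_spacing
    interval <- frame_interval %||% sc$frame_interval_ms
  }
  if (is.null(spacing))
    stop("pixel spacing unavailable: provide a JSON sidecar ",
         shQuote(sidecarPath(path)),
         " with pixel_spacing, or pass pixel_spacing=")
  if (is.null(interval))
    stop("frame interval unavailable: provide a JSON sidecar ",
         shQuote(sidecarPath(path)),
         " with frame_interval_ms, or pass frame_interval=")
  id <- sc$identifier %||% file_path_sans_ext(basename(path))
  cineSequence(arr, spacing, interval, identifier = id)
}

#' Write a cine sequence to disk
#'
#' NIfTI stores the frames losslessly as doubles with spacing/timing in
#' `pixdim`; TIFF stores 16-bit grayscale on a [0, 1] scale (intensity / 255).
#' A JSON sidecar with spacing, timing and identifier is written alongside in
#' both cases.
#'
#' @param seq a [CineSequence-class].
#' @param path output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @param datatype NIfTI on-disk type: `"double"` (lossless, default),
#'   `"float"` or `"uint8"` (compact; the pipeline uses these for sequences
#'   and label stacks).
#' @return `path`, invisibly.
#' @export
writeSequence <- function(seq, path,
                          datatype = c("double", "float", "uint8")) {
  stopifnot(is(seq, "CineSequence"))
  datatype <- match.arg(datatype)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(frames(seq))
    RNifti::pixdim(img) <- c(pixelSpacing(seq), frameInterval(seq))
    RNifti::writeNifti(img, path, datatype = datatype)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(nFrames(seq)),
                    function(i) pmin(pmax(getFrame(seq, i) / 255, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else stop("unsupported output format: ", path)
  writeSidecar(path, seq)
  invisible(path)
}

#' Write segmentation outputs for one sequence
#'
#' Masks go out as a rows x cols x frames label stack (0 = background,
#' 1 = lumen) in NIfTI or TIFF; metrics as CSV with the fixed header
#' `frame,time_ms,area_mm2,ap_mm,tx_mm`. Re-running with identical inputs
#' reproduces identical files.
#'
#' @param id sequence identifier (used as the file stem).
#' @param masks list of [AirwayMask-class], one per frame.
#' @param metrics data.frame from [sequenceMetrics()].
#' @param dir output directory (created if needed).
#' @param mask_format `"nifti"` or `"tiff"`.
#' @param spacing,interval physical metadata echoed into the mask sidecar.
#' @return Named character vector of the files written.
#' @export
writeOutputs <- function(id, masks, metrics, dir, mask_format = c("nifti", "tiff"),
                         spacing = c(1, 1), interval = 1) {
  mask_format <- match.arg(mask_format)
  if (length(masks) != nrow(metrics))
    stop("masks (", length(masks), ") and metrics rows (", nrow(metrics),
         ") must match")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack <- array(0, c(dim(maskMatrix(masks[[1L]])), length(masks)))
  for (i in seq_along(masks)) stack[, , i] <- maskMatrix(masks[[i]]) * 1
  ext <- if (mask_format == "nifti") ".nii" else ".tif"
  maskfile <- file.path(dir, paste0(id, "_mask", ext))
  mseq <- cineSequence(stack * 255, spacing, interval,
                       identifier = paste0(id, "_mask"))
  writeSequence(mseq, maskfile,
                datatype = if (mask_format == "nifti") "uint8" else "double")
  csvfile <- file.path(dir, paste0(id, "_metrics.csv"))
  writeMetricsCsv(metrics, csvfile)
  c(mask = maskfile, metrics = csvfile)
}

metricsColumns <- c("frame", "time_ms", "area_mm2", "ap_mm", "tx_mm")

#' Write / read a per-frame metrics table as CSV
#'
#' The column set `frame,time_ms,area_mm2,ap_mm,tx_mm` is fixed so downstream
#' stages can rely on it bit-exactly.
#'
#' @param metrics data.frame with the columns above.
#' @param path CSV path.
#' @return `writeMetricsCsv()`: the path, invisibly. `readMetricsCsv()`: the
#'   data.frame.
#' @export
writeMetricsCsv <- function(metrics, path) {
  stopifnot(identical(names(metrics), metricsColumns))
  write.csv(format(metrics, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMetricsCsv
#' @export
readMetricsCsv <- function(path) {
  tab <- read.csv(path)
  if (!identical(names(tab), metricsColumns))
    stop("metrics CSV ", path, " must have columns ",
         paste(metricsColumns, collapse = ","))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
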