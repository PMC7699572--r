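#' CineSequence: an ordered stack of 2-D frames with physical metadata
#'
#' The unit of segmentation: a single axial imaging plane acquired repeatedly
#' during continuous breathing. Rows run anterior to posterior (AP axis),
#' columns run transverse (TX axis). Frames are stored as a numeric
#' rows x cols x frames array in grayscale units (nominally 0-255).
#'
#' @slot frames numeric array, rows x cols x frames; frame order is strictly
#'   temporal.
#' @slot pixelSpacing numeric(2), mm per pixel along (row, col). May be
#'   anisotropic.
#' @slot frameInterval numeric(1), ms between consecutive frames.
#' @slot identifier character(1), free-text sequence id.
#'
#' @seealso [cineSequence()] constructor, [readSequence()], [segmentSequence()]
#' @exportClass CineSequence
setClass("CineSequence",
  representation(
    frames        = "array",
    pixelSpacing  = "numeric",
    frameInterval = "numeric",
    identifier    = "character"
  )
)

setValidity("CineSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a rows x cols x frames array")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (mm/row-px, mm/col-px)")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive value (ms)")
  if (length(object@identifier) != 1L)
    msg <- c(msg, "identifier must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CineSequence
#'
#' @param frames numeric array rows x cols x frames, or a list of equally
#'   sized matrices (stacked in list order).
#' @param pixelSpacing mm per pixel along (row, col); a single value is
#'   recycled to isotropic spacing.
#' @param frameInterval ms between frames.
#' @param identifier sequence id.
#' @return A [CineSequence-class] object.
#' @examples
#' frames <- array(150, c(8, 8, 3))
#' cineSequence(frames, pixelSpacing = 0.5, frameInterval = 350)
#' @export
cineSequence <- function(frames, pixelSpacing, frameInterval,
                         identifier = "sequence") {
  if (is.list(frames)) {
    shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop("all frames must have the same shape; got: ",
           paste(unique(shapes), collapse = ", "))
    frames <- array(unlist(frames),
                    c(dim(frames[[1L]]), length(frames)))
  }
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("CineSequence", frames = frames,
      pixelSpacing = as.numeric(pixelSpacing),
      frameInterval = as.numeric(frameInterval),
      identifier = as.character(identifier))
}

#' ProfileBounds: rectangular airway search limits from profile peaks
#'
#' The rectangular limits of the airway boundary found from the 1-D intensity
#' profiles through the seed: the nearest sufficiently prominent local maximum
#' on each side of the seed along the AP (row) and TX (column) axes. When no
#' qualifying peak exists on a side, the image border is the limit.
#'
#' @slot rowLo,rowHi integer, AP extent (inclusive, 1-based).
#' @slot colLo,colHi integer, TX extent (inclusive, 1-based).
#' @slot prominences numeric(4), peak prominences (grayscale) in the order
#'   rowLo, rowHi, colLo, colHi; NA where the border fallback was used.
#' @exportClass ProfileBounds
setClass("ProfileBounds",
  representation(
    rowLo = "integer", rowHi = "integer",
    colLo = "integer", colHi = "integer",
    prominences = "numeric"
  )
)

setValidity("ProfileBounds", function(object) {
  msg <- character()
  if (object@rowLo > object@rowHi) msg <- c(msg, "rowLo > rowHi")
  if (object@colLo > object@colHi) msg <- c(msg, "colLo > colHi")
  if (any(c(object@rowLo, object@colLo) < 1L))
    msg <- c(msg, "bounds must be positive indices")
  if (length(msg)) msg else TRUE
})

#' AirwayMask: per-frame binary lumen labeling
#'
#' The segmented airway lumen for a single frame: pixels below the threshold,
#' inside the profile bounds, connected to the seed (plus the rectangular
#' completion rule, see [regionGrow()]).
#'
#' @slot mask logical matrix, TRUE = lumen.
#' @slot bounds the [ProfileBounds-class] used.
#' @slot threshold numeric(1), grayscale threshold used.
#' @slot empty logical(1), TRUE when no lumen pixel was found (closed airway).
#' @exportClass AirwayMask
setClass("AirwayMask",
  representation(
    mask      = "matrix",
    bounds    = "ProfileBounds",
    threshold = "numeric",
    empty     = "logical"
  )
)

setValidity("AirwayMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@empty && any(object@mask))
    msg <- c(msg, "empty flag set but mask has TRUE pixels")
  if (!object@empty && !any(object@mask))
    msg <- c(msg, "mask has no TRUE pixels but empty flag not set")
  if (length(msg)) msg else TRUE
})
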