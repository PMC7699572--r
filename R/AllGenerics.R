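#' @name CineSequence-accessors
#' @title Accessors for CineSequence and AirwayMask objects
#' @param x a [CineSequence-class], [AirwayMask-class] or
#'   [ProfileBounds-class] object.
#' @param i frame index (1-based).
#' @description `frames()` returns the rows x cols x frames array;
#'   `getFrame()` a single frame matrix; `nFrames()` the frame count;
#'   `pixelSpacing()` mm/pixel along (row, col); `frameInterval()` ms between
#'   frames; `identifier()` the sequence id; `maskMatrix()`, `maskBounds()`,
#'   `maskThreshold()` and `isEmptyMask()` the AirwayMask slots;
#'   `boundsRange()` the (rowLo, rowHi, colLo, colHi) vector.
NULL

#' @rdname CineSequence-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("maskBounds", function(x) standardGeneric("maskBounds"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("isEmptyMask", function(x) standardGeneric("isEmptyMask"))
#' @rdname CineSequence-accessors
#' @export
setGeneric("boundsRange", function(x) standardGeneric("boundsRange"))

#' @rdname CineSequence-accessors
setMethod("frames", "CineSequence", function(x) x@frames)
#' @rdname CineSequence-accessors
setMethod("getFrame", "CineSequence", function(x, i) {
  stopifnot(i >= 1L, i <= dim(x@frames)[3L])
  x@frames[, , i]
})
#' @rdname CineSequence-accessors
setMethod("nFrames", "CineSequence", function(x) dim(x@frames)[3L])
#' @rdname CineSequence-accessors
setMethod("pixelSpacing", "CineSequence", function(x) x@pixelSpacing)
#' @rdname CineSequence-accessors
setMethod("frameInterval", "CineSequence", function(x) x@frameInterval)
#' @rdname CineSequence-accessors
setMethod("identifier", "CineSequence", function(x) x@identifier)

#' @rdname CineSequence-accessors
setMethod("maskMatrix", "AirwayMask", function(x) x@mask)
#' @rdname CineSequence-accessors
setMethod("maskBounds", "AirwayMask", function(x) x@bounds)
#' @rdname CineSequence-accessors
setMethod("maskThreshold", "AirwayMask", function(x) x@threshold)
#' @rdname CineSequence-accessors
setMethod("isEmptyMask", "AirwayMask", function(x) x@empty)
#' @rdname CineSequence-accessors
setMethod("boundsRange", "ProfileBounds", function(x)
  c(rowLo = x@rowLo, rowHi = x@rowHi, colLo = x@colLo, colHi = x@colHi))

setMethod("show", "CineSequence", function(object) {
  d <- dim(object@frames)
  cat("CineSequence \"", object@identifier, "\"\n", sep = "")
  cat("  ", d[1L], " x ", d[2L], " pixels, ", d[3L], " frames\n", sep = "")
  cat("  pixel spacing: ", paste(signif(object@pixelSpacing, 4), collapse = " x "),
      " mm;  frame interval: ", object@frameInterval, " ms\n", sep = "")
})

setMethod("show", "AirwayMask", function(object) {
  cat("AirwayMask: ", sum(object@mask), " lumen pixels",
      if (object@empty) " (empty)" else "",
      "; threshold ", signif(object@threshold, 4), "\n", sep = "")
  b <- object@bounds
  cat("  bounds rows [", b@rowLo, ", ", b@rowHi, "], cols [",
      b@colLo, ", ", b@colHi, "]\n", sep = "")
})

setMethod("show", "ProfileBounds", function(object) {
  cat("ProfileBounds rows [", object@rowLo, ", ", object@rowHi,
      "], cols [", object@colLo, ", ", object@colHi, "]\n", sep = "")
})
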