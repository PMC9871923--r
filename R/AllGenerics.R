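#' Accessors for campariq objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a campariq S4 object.
#' @return \code{cells} returns the per-cell ground-truth data.frame;
#'   \code{nCells} the number of cells; \code{frameShape} the integer
#'   (rows, cols) of the frame; \code{greenChannel}/\code{redChannel} the
#'   3-d (frame, row, col) arrays of a \linkS4class{TwoChannelStack};
#'   \code{wavelength} the excitation wavelength in nm;
#'   \code{nTrials} the number of trials of a \linkS4class{StimulusProtocol}.
#' @name accessors
#' @aliases cells nCells frameShape greenChannel redChannel wavelength nTrials
#' @examples
#' pop <- generatePopulation(12, c(64, 64), fractionTuned = 0.25, seed = 1)
#' nCells(pop)
#' head(cells(pop))
NULL

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("frameShape", function(x) standardGeneric("frameShape"))

#' @rdname accessors
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))

#' @rdname accessors
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))

#' @rdname accessors
#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
setMethod("cells", "ScenePopulation", function(x) x@cells)

#' @rdname accessors
setMethod("nCells", "ScenePopulation", function(x) nrow(x@cells))

#' @rdname accessors
setMethod("frameShape", "ScenePopulation", function(x) x@frameShape)

#' @rdname accessors
setMethod("greenChannel", "TwoChannelStack", function(x) x@green)

#' @rdname accessors
setMethod("redChannel", "TwoChannelStack", function(x) x@red)

#' @rdname accessors
setMethod("wavelength", "TwoChannelStack", function(x) x@wavelength)

#' @rdname accessors
setMethod("nTrials", "StimulusProtocol",
          function(x) x@nDirections * x@nRepetitions)
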