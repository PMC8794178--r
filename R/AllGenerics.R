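#' @rdname FieldImage-class
#' @param x a \code{FieldImage}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FieldImage-class
#' @param role channel role name
#' @param plane plane index (1-based)
#' @export
setGeneric("getChannel", function(x, role, plane = 1L)
    standardGeneric("getChannel"))

#' @rdname GroundTruth-class
#' @param x a \code{GroundTruth} or \code{CellSet}
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname GroundTruth-class
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' @rdname RegionLabelMap-class
#' @param x a \code{RegionLabelMap}
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname CellSet-class
#' @param x a \code{CellSet}
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname CellSet-class
#' @param value replacement manifest
#' @export
setGeneric("manifest<-", function(x, value) standardGeneric("manifest<-"))

#' @rdname CellSet-class
#' @param key crop channel key
#' @export
setGeneric("crops", function(x, key) standardGeneric("crops"))

#' @rdname EvaluationResult-class
#' @param x an \code{EvaluationResult}
#' @export
setGeneric("aucTable", function(x) standardGeneric("aucTable"))

#' @rdname LabelModel-class
#' @param x a \code{LabelModel}
#' @export
setGeneric("unusedInterval", function(x) standardGeneric("unusedInterval"))
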