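#' @rdname FieldImage-class
setMethod("channelNames", "FieldImage", function(x) names(x@channels))

#' @rdname FieldImage-class
setMethod("getChannel", "FieldImage", function(x, role, plane = 1L) {
    if (!role %in% names(x@channels))
        stop("no channel with role '", role, "'")
    x@channels[[role]][, , plane]
})

#' @rdname GroundTruth-class
setMethod("cells", "GroundTruth", function(x) x@cells)

#' @rdname GroundTruth-class
setMethod("labelMask", "GroundTruth", function(x) x@mask)

#' @rdname RegionLabelMap-class
setMethod("regionTable", "RegionLabelMap", function(x) x@table)

#' @rdname RegionLabelMap-class
setMethod("labelMask", "RegionLabelMap", function(x) x@labels)

#' @rdname CellSet-class
setMethod("manifest", "CellSet", function(x) x@manifest)

#' @rdname CellSet-class
setMethod("manifest<-", "CellSet", function(x, value) {
    x@manifest <- value
    validObject(x)
    x
})

#' @rdname CellSet-class
setMethod("crops", "CellSet", function(x, key) {
    if (!key %in% names(x@crops)) stop("no crop channel '", key, "'")
    x@crops[[key]]
})

#' @rdname CellSet-class
setMethod("cells", "CellSet", function(x) x@manifest)

#' @rdname CellSet-class
#' @param object a \code{CellSet}
setMethod("length", "CellSet", function(x) nrow(x@manifest))

#' Subset a CellSet by cell index
#' @param x a \code{CellSet}
#' @param i integer or logical index over cells
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "CellSet", function(x, i, j, ..., drop = FALSE) {
    idx <- seq_len(nrow(x@manifest))[i]
    new("CellSet",
        crops = lapply(x@crops, function(a) a[, , idx, drop = FALSE]),
        manifest = x@manifest[idx, , drop = FALSE],
        cropSize = x@cropSize)
})

#' @rdname LabelModel-class
setMethod("unusedInterval", "LabelModel", function(x) x@unusedInterval)

#' @rdname EvaluationResult-class
setMethod("aucTable", "EvaluationResult", function(x) x@table)

setMethod("show", "FieldImage", function(object) {
    d <- dim(object@channels[[1]])
    cat(sprintf("FieldImage dish %d field %d: %d x %d px, %d plane(s)\n",
                object@dish, object@field, d[1], d[2], d[3]))
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d cells (%s)\n", nrow(object@cells),
        paste(sprintf("%s=%d", names(table(object@cells$type)),
                      as.integer(table(object@cells$type))), collapse = ", ")))
})

setMethod("show", "RegionLabelMap", function(object) {
    cat(sprintf("RegionLabelMap: %d regions over %d x %d px\n",
                nrow(object@table), nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "CellSet", function(object) {
    cat(sprintf("CellSet: %d cells, %d crop channel(s) [%s], %d x %d px\n",
                nrow(object@manifest), length(object@crops),
                paste(names(object@crops), collapse = ", "),
                object@cropSize, object@cropSize))
    if ("label" %in% colnames(object@manifest)) {
        tab <- table(object@manifest$label)
        cat("  labels:", paste(sprintf("%s=%d", names(tab),
                                       as.integer(tab)), collapse = ", "), "\n")
    }
})

setMethod("show", "LabelModel", function(object) {
    cat(sprintf(paste0("LabelModel (2-component Gaussian mixture on F, ",
                       "n = %d)\n"), object@n))
    cat(sprintf("  LMPP:  mean %.3f sd %.3f weight %.3f\n",
                object@means[1], object@sds[1], object@weights[1]))
    cat(sprintf("  proB:  mean %.3f sd %.3f weight %.3f\n",
                object@means[2], object@sds[2], object@weights[2]))
    cat(sprintf("  unused interval: (%.3f, %.3f), posterior threshold %.2f\n",
                object@unusedInterval[1], object@unusedInterval[2],
                object@threshold))
})

setMethod("show", "CNNClassifier", function(object) {
    cat(sprintf("CNNClassifier: %d input channel(s) [%s], best epoch %d/%d\n",
                length(object@channels),
                paste(object@channels, collapse = ", "),
                object@bestEpoch, nrow(object@history)))
})

setMethod("show", "SizeSVM", function(object) {
    cat("SizeSVM: RBF-kernel SVM on z-scored cell size (gamma = 1)\n")
})

setMethod("show", "EvaluationResult", function(object) {
    cat("EvaluationResult:\n")
    print(as.data.frame(object@table))
})
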