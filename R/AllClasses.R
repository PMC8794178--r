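#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' FieldImage: one multi-channel microscopy field
#'
#' Container for a single field of view. Each channel is a numeric array
#' \code{height x width x planes}; planes index focal offsets (z-stack) or
#' time points, as described by \code{focalOffsets} and \code{timeIndices}.
#' Channel roles follow the four-channel acquisition layout of the emulated
#' microscope: \code{"ph"} (phase-contrast-like segmentation channel),
#' \code{"dic"} and \code{"bf"} (auxiliary transmitted-light channels) and
#' \code{"marker"} (fluorescence marker, used only for labelling).
#'
#' @slot channels named list of numeric arrays, all with identical dimensions.
#' @slot dish integer dish identifier.
#' @slot field integer field identifier within the dish.
#' @slot focalOffsets numeric vector of focal offsets (micrometres), one per
#'   z-plane; the in-focus reference plane has offset 0.
#' @slot timeIndices integer vector of time-point indices, one per time plane.
#' @slot pixelSize physical pixel size in nanometres.
#' @export
setClass("FieldImage",
    representation(channels = "list", dish = "integer", field = "integer",
                   focalOffsets = "numeric", timeIndices = "integer",
                   pixelSize = "numeric"))

setValidity("FieldImage", function(object) {
    ch <- object@channels
    if (length(ch) == 0L) return("no channels")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
        return("channels must be named")
    d <- dim(ch[[1]])
    for (x in ch) {
        if (!is.array(x) || length(dim(x)) != 3L)
            return("each channel must be a 3-d array (h x w x planes)")
        if (!identical(dim(x), d)) return("channel dimensions differ")
        if (any(!is.finite(x))) return("non-finite pixel value")
    }
    TRUE
})

#' GroundTruth: per-cell truth for one synthetic field
#'
#' @slot cells a \code{DataFrame} with one row per generated cell
#'   (cell_id, dish, field, cx, cy, type, area_px, marker_total).
#' @slot mask integer label-mask matrix; value k marks pixels of cell_id k
#'   within the field, 0 is background.
#' @export
setClass("GroundTruth",
    representation(cells = "DataFrame", mask = "matrix"))

setValidity("GroundTruth", function(object) {
    need <- c("cell_id", "dish", "field", "cx", "cy", "type",
              "area_px", "marker_total")
    if (!all(need %in% colnames(object@cells)))
        return(paste("cells must have columns:", paste(need, collapse = ", ")))
    ids <- sort(unique(as.vector(object@mask)))
    ids <- ids[ids != 0L]
    if (!setequal(ids, object@cells$cell_id))
        return("mask labels and cell ids are not a bijection")
    TRUE
})

#' RegionLabelMap: labelled segmentation result for one field
#'
#' @slot labels integer matrix, 0 background, regions labelled with
#'   consecutive positive integers.
#' @slot table \code{DataFrame} with columns label, area_px, cx, cy,
#'   bbox_r0, bbox_r1, bbox_c0, bbox_c1 (1-based, inclusive).
#' @export
setClass("RegionLabelMap",
    representation(labels = "matrix", table = "DataFrame"))

setValidity("RegionLabelMap", function(object) {
    tab <- object@table
    labs <- tab$label
    if (length(labs) && !identical(as.integer(labs), seq_along(labs)))
        return("labels must be consecutive positive integers")
    cnt <- tabulate(object@labels[object@labels > 0L], nbins = length(labs))
    if (length(labs) && !identical(as.integer(tab$area_px), cnt))
        return("table areas disagree with label-mask pixel counts")
    TRUE
})

#' CellSet: a collection of per-cell multi-channel crops
#'
#' Crops are square windows (default 150 x 150) centred on segmented-region
#' centroids. \code{crops} is a named list keyed by channel role (and plane
#' suffix for off-focus or time planes, e.g. \code{"dic.z+1.2"}), each entry a
#' numeric array \code{size x size x n}. The \code{"contour"} entry holds the
#' binary crop of the generating region itself; \code{"marker"} holds the
#' flat-field-corrected fluorescence crop used only for labelling.
#'
#' @slot crops named list of arrays \code{size x size x n}.
#' @slot manifest \code{DataFrame} with one row per cell: cell_id, dish,
#'   field, cx, cy, area_px, plus columns filled downstream (l, F,
#'   posterior_proB, label) and, for synthetic data, true_type.
#' @slot cropSize integer crop edge length in pixels.
#' @export
setClass("CellSet",
    representation(crops = "list", manifest = "DataFrame",
                   cropSize = "integer"))

setValidity("CellSet", function(object) {
    n <- nrow(object@manifest)
    s <- object@cropSize
    for (nm in names(object@crops)) {
        d <- dim(object@crops[[nm]])
        if (length(d) != 3L || d[1] != s || d[2] != s || d[3] != n)
            return(sprintf("crop array '%s' must be %d x %d x %d", nm, s, s, n))
    }
    TRUE
})

#' LabelModel: two-component Gaussian mixture over the marker statistic F
#'
#' The high-mean component maps to the marker-positive type ("proB"), the
#' low-mean component to "LMPP". Cells whose posterior is below the
#' threshold for both components fall in the unused interval.
#'
#' @slot means,sds,weights numeric length-2 vectors, ordered (LMPP, proB),
#'   i.e. increasing means.
#' @slot threshold posterior threshold for assignment (default 0.8).
#' @slot unusedInterval numeric length-2: the F range where both posteriors
#'   fall below \code{threshold}.
#' @slot converged logical EM convergence flag.
#' @slot logLik final observed-data log-likelihood.
#' @slot n number of cells used in the fit.
#' @slot seed seed used for the k-means initialisation.
#' @export
setClass("LabelModel",
    representation(means = "numeric", sds = "numeric", weights = "numeric",
                   threshold = "numeric", unusedInterval = "numeric",
                   converged = "logical", logLik = "numeric", n = "integer",
                   seed = "integer"))

setValidity("LabelModel", function(object) {
    if (length(object@means) != 2L) return("two components required")
    if (any(object@sds <= 0)) return("component sds must be > 0")
    if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
    if (object@means[1] > object@means[2])
        return("components must be ordered by increasing mean (LMPP, proB)")
    TRUE
})

#' CNNClassifier: a trained convolutional network
#'
#' @slot spec architecture description (list; see \code{\link{cnnSpec}}).
#' @slot train training protocol used (list; see \code{\link{trainSpec}}).
#' @slot weights list of parameter matrices at the best validation epoch.
#' @slot channels character vector of crop keys the model consumes, in order.
#' @slot history data.frame (epoch, train_loss, val_loss).
#' @slot bestEpoch epoch whose parameters are stored.
#' @export
setClass("CNNClassifier",
    representation(spec = "list", train = "list", weights = "list",
                   channels = "character", history = "data.frame",
                   bestEpoch = "integer"))

#' SizeSVM: RBF support-vector machine over cell size
#'
#' @slot model fitted \code{e1071::svm} object.
#' @slot center,scale training-fold mean and sd used to z-score areas.
#' @export
setClass("SizeSVM",
    representation(model = "ANY", center = "numeric", scale = "numeric"))

#' EvaluationResult: dish-level cross-validation outcome
#'
#' @slot table \code{DataFrame}: one row per validation (validation,
#'   test_dish, auc, n_train, n_test, epochs).
#' @slot rocs list of per-validation ROC data.frames (fpr, tpr).
#' @slot config list describing the input configuration (channels or
#'   classifier kind, focal offset, training size, seeds).
#' @export
setClass("EvaluationResult",
    representation(table = "DataFrame", rocs = "list", config = "list"))
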