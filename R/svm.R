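#' Cell-size SVM baseline
#'
#' Radial-basis-function support vector machine over the single feature
#' cell size (pixel area), the non-image baseline classifier. Areas are
#' z-scored with training-fold statistics before the kernel (kernel
#' coefficient gamma = 1 acts on the standardised scale; on raw pixel
#' counts of order 10^3 every kernel entry would vanish). The continuous
#' decision value is used for ROC/AUC scoring.
#'
#' @param areas numeric vector of cell areas (px).
#' @param labels factor/character with two classes (\code{"LMPP"},
#'   \code{"proB"}).
#' @param gamma RBF kernel coefficient on the z-scored scale.
#' @return a \code{\link{SizeSVM}}.
#' @export
trainSizeSVM <- function(areas, labels, gamma = 1) {
    labels <- factor(as.character(labels), levels = c("LMPP", "proB"))
    if (nlevels(droplevels(labels)) < 2L)
        stop("training labels contain a single class")
    ctr <- mean(areas)
    scl <- stats::sd(areas)
    if (!is.finite(scl) || scl == 0) scl <- 1
    z <- (areas - ctr) / scl
    fit <- e1071::svm(x = matrix(z, ncol = 1), y = labels,
                      kernel = "radial", gamma = gamma, scale = FALSE)
    new("SizeSVM", model = fit, center = ctr, scale = scl)
}

#' Decision values of a SizeSVM
#'
#' Signed so larger values favour the marker-positive class
#' (\code{"proB"}), making them directly usable as ROC scores.
#'
#' @param object a \code{\link{SizeSVM}}.
#' @param areas numeric vector of cell areas (px).
#' @return numeric decision values.
#' @export
decisionValues <- function(object, areas) {
    z <- matrix((areas - object@center) / object@scale, ncol = 1)
    pr <- stats::predict(object@model, z, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    ## e1071 orients the decision value toward the first class seen in
    ## training; flip so positive always means proB
    if (grepl("^proB", colnames(attr(pr, "decision.values"))[1])) dv else -dv
}
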