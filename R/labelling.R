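#' Per-cell marker total within the labelling radius
#'
#' Sum of flattened marker-crop pixels strictly closer than \code{radius}
#' pixels to the crop centre.
#'
#' @param crop square numeric matrix (a marker crop).
#' @param radius labelling radius in pixels.
#' @return the total \code{l}; cells with non-positive totals are excluded
#'   downstream.
#' @export
markerTotal <- function(crop, radius = 30) {
    stopifnot(nrow(crop) == ncol(crop))
    sum(crop[discMask(nrow(crop), radius)])
}

#' Log relative marker intensity
#'
#' \code{F_i = ln(l_i / max(l))}, the per-cell marker statistic; the
#' maximum is taken over the whole experiment (all dishes pooled), so
#' \code{F <= 0} with equality exactly at the brightest cell.
#'
#' @param l vector of positive per-cell marker totals.
#' @return vector of \code{F} values.
#' @export
logRelativeIntensity <- function(l) {
    if (!length(l)) stop("empty marker-total vector")
    if (any(l <= 0)) stop("all marker totals must be positive")
    log(l) - log(max(l))
}

#' Fit the two-component Gaussian mixture label model
#'
#' EM fit of a univariate two-component Gaussian mixture on the marker
#' statistic \code{F}, initialised by k-means under a fixed seed. Cells are
#' assigned the label of the component whose posterior probability is at
#' least \code{threshold}; cells below the threshold for both components
#' are \code{"unused"}. The high-mean component is the marker-positive
#' type, \code{"proB"}; the low-mean component is \code{"LMPP"}.
#'
#' @param F numeric vector of marker statistics (>= 2 distinct values).
#' @param threshold posterior threshold for assignment.
#' @param seed seed for the k-means initialisation.
#' @param maxIter EM iteration cap.
#' @param tol log-likelihood convergence tolerance.
#' @return a list with elements \code{model} (a \code{\link{LabelModel}}),
#'   \code{labels} (factor of \code{"LMPP"}, \code{"proB"},
#'   \code{"unused"}) and \code{posteriorProB}.
#' @export
fitLabelGMM <- function(F, threshold = 0.8, seed = 1L, maxIter = 2000L,
                        tol = 1e-6) {
    F <- as.numeric(F)
    if (length(unique(F)) < 2L)
        stop("need >= 2 distinct F values to fit a mixture")
    km <- withSeed(seed, stats::kmeans(F, centers = 2L, nstart = 5L))
    ord <- order(km$centers)
    mu <- as.numeric(km$centers[ord])
    grp <- match(km$cluster, ord)
    sd0 <- vapply(1:2, function(k) stats::sd(F[grp == k]), 0)
    sd0[!is.finite(sd0) | sd0 < 1e-6] <- stats::sd(F) / 4
    w <- tabulate(grp, 2) / length(F)
    ll <- -Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        dens <- cbind(w[1] * stats::dnorm(F, mu[1], sd0[1]),
                      w[2] * stats::dnorm(F, mu[2], sd0[2]))
        tot <- rowSums(dens)
        tot[tot == 0] <- .Machine$double.xmin
        llNew <- sum(log(tot))
        post <- dens / tot
        nk <- colSums(post)
        if (any(nk < 1e-8)) stop("degenerate mixture component (empty)")
        w <- nk / length(F)
        mu <- colSums(post * F) / nk
        sd0 <- sqrt(colSums(post * (outer(F, mu, "-"))^2) / nk)
        if (any(sd0 < 1e-8))
            stop("degenerate mixture component (sd below floor)")
        if (is.finite(ll) && abs(llNew - ll) < tol) {
            converged <- TRUE
            ll <- llNew
            break
        }
        ll <- llNew
    }
    if (!converged)
        stop(sprintf(paste0("EM did not converge in %d iterations ",
                            "(logLik %.6f, means %.3f/%.3f)"),
                     maxIter, ll, mu[1], mu[2]))
    if (mu[1] > mu[2]) {           # order components (LMPP low, proB high)
        mu <- rev(mu); sd0 <- rev(sd0); w <- rev(w)
    }
    postB <- posteriorProB(F, mu, sd0, w)
    labels <- factor(ifelse(postB >= threshold, "proB",
                     ifelse(1 - postB >= threshold, "LMPP", "unused")),
                     levels = c("LMPP", "proB", "unused"))
    model <- new("LabelModel", means = mu, sds = sd0, weights = w,
                 threshold = threshold,
                 unusedInterval = unusedIntervalOf(mu, sd0, w, threshold),
                 converged = converged, logLik = ll, n = length(F),
                 seed = as.integer(seed))
    list(model = model, labels = labels, posteriorProB = postB)
}

posteriorProB <- function(F, mu, sd0, w) {
    a <- w[1] * stats::dnorm(F, mu[1], sd0[1])
    b <- w[2] * stats::dnorm(F, mu[2], sd0[2])
    tot <- a + b
    tot[tot == 0] <- .Machine$double.xmin
    b / tot
}

## The F interval between the component means where both posteriors fall
## below the threshold (empty when the components barely overlap there).
unusedIntervalOf <- function(mu, sd0, w, threshold) {
    grid <- seq(mu[1], mu[2], length.out = 4096L)
    p <- posteriorProB(grid, mu, sd0, w)
    un <- grid[p < threshold & 1 - p < threshold]
    if (!length(un)) return(c(NA_real_, NA_real_))
    c(min(un), max(un))
}

#' Label an experiment's cells from the marker channel
#'
#' Computes the per-cell marker total (radius 30 px around the crop
#' centre), the experiment-wide log relative intensity \code{F}, fits the
#' mixture label model and writes \code{l}, \code{F},
#' \code{posterior_proB} and \code{label} into the manifest. Cells with
#' non-positive marker totals are excluded (label \code{NA}) and do not
#' enter the fit.
#'
#' @param cellSet an experiment-level \code{\link{CellSet}} containing a
#'   \code{"marker"} crop channel.
#' @param radius labelling radius (px).
#' @param threshold posterior threshold.
#' @param seed seed for the mixture initialisation.
#' @return a list: \code{cellSet} (manifest augmented), \code{model}.
#' @export
labelCells <- function(cellSet, radius = 30, threshold = 0.8, seed = 1L) {
    mk <- crops(cellSet, "marker")
    n <- dim(mk)[3]
    mask <- discMask(dim(mk)[1], radius)
    l <- vapply(seq_len(n), function(i) sum(mk[, , i][mask]), 0)
    usable <- l > 0
    if (!any(usable)) stop("no cell has a positive marker total")
    F <- rep(NA_real_, n)
    F[usable] <- logRelativeIntensity(l[usable])
    fit <- fitLabelGMM(F[usable], threshold = threshold, seed = seed)
    man <- manifest(cellSet)
    man$l <- l
    man$F <- F
    man$posterior_proB <- NA_real_
    man$posterior_proB[usable] <- fit$posteriorProB
    man$label <- factor(NA, levels = c("LMPP", "proB", "unused"))
    man$label[usable] <- fit$labels
    manifest(cellSet) <- man
    list(cellSet = cellSet, model = fit$model)
}
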