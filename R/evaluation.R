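#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: the probability that a random
#' positive scores above a random negative, ties counted half.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param truth binary truth: logical, 0/1, or factor with levels
#'   LMPP/proB (proB positive).
#' @return the AUC in [0, 1].
#' @export
computeAUC <- function(scores, truth) {
    truth <- toBinaryTruth(truth)
    n1 <- sum(truth); n0 <- sum(!truth)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute an AUC")
    r <- rank(scores)   # midranks for ties
    (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

toBinaryTruth <- function(truth) {
    if (is.factor(truth) || is.character(truth)) {
        as.character(truth) == "proB"
    } else if (is.logical(truth)) truth
    else truth == 1
}

## ROC points (fpr, tpr) at every distinct score threshold.
rocPoints <- function(scores, truth) {
    truth <- toBinaryTruth(truth)
    ord <- order(scores, decreasing = TRUE)
    tp <- cumsum(truth[ord]); fp <- cumsum(!truth[ord])
    keep <- c(diff(scores[ord]) != 0, TRUE)
    data.frame(fpr = c(0, fp[keep] / sum(!truth)),
               tpr = c(0, tp[keep] / sum(truth)))
}

#' Dish-level cross-validation of a classifier
#'
#' Validation \code{n} holds out dish \code{n} as the test set and trains
#' on all other dishes. The positive class is \code{"proB"}, scored by its
#' softmax probability (CNN) or the SVM decision value.
#'
#' @param cellSet a labelled, balanced \code{\link{CellSet}} spanning >= 2
#'   dishes.
#' @param classifier \code{"cnn"} or \code{"svm"} (cell-size baseline).
#' @param channels crop-channel keys stacked as CNN input (ignored for
#'   SVM). The marker channel is refused.
#' @param train a \code{\link{trainSpec}} (CNN only).
#' @param maskRadius circular-mask radius for preprocessing.
#' @param verbose print per-epoch training losses.
#' @return an \code{\link{EvaluationResult}}.
#' @export
crossValidate <- function(cellSet, classifier = c("cnn", "svm"),
                          channels = "dic", train = trainSpec(),
                          maskRadius = 50, verbose = FALSE) {
    classifier <- match.arg(classifier)
    man <- manifest(cellSet)
    dishes <- sort(unique(man$dish))
    if (length(dishes) < 2L) stop("cross-validation needs >= 2 dishes")
    labels <- droplevels(factor(man$label, levels = c("LMPP", "proB")))
    if (any(is.na(labels))) stop("cellSet must contain only labelled cells")
    prep <- NULL
    if (classifier == "cnn") {
        prep <- prepareInputs(cellSet, channels, radius = maskRadius)
        if (length(attr(prep, "dropped")))
            stop("cells dropped during preprocessing; filter them first")
    }
    rows <- list(); rocs <- list()
    for (vi in seq_along(dishes)) {
        testIdx <- which(man$dish == dishes[vi])
        trainIdx <- which(man$dish != dishes[vi])
        truthTest <- labels[testIdx]
        if (nlevels(droplevels(truthTest)) < 2L)
            stop(sprintf("test dish %d has a single class", dishes[vi]))
        if (classifier == "cnn") {
            fold <- trainSpec(alpha = train$alpha, beta1 = train$beta1,
                              beta2 = train$beta2, eps = train$eps,
                              eta = train$eta, batchSize = train$batchSize,
                              valFraction = train$valFraction,
                              patience = train$patience,
                              maxEpochs = train$maxEpochs,
                              initSeed = subSeed(train$initSeed, vi),
                              orderSeed = subSeed(train$orderSeed, vi),
                              splitSeed = subSeed(train$splitSeed, vi))
            model <- trainCNN(prep$x[, , , trainIdx, drop = FALSE],
                              labels[trainIdx], train = fold,
                              channels = channels, verbose = verbose)
            sc <- predictProba(model,
                               prep$x[, , , testIdx, drop = FALSE])[, "proB"]
            epochs <- nrow(model@history)
        } else {
            model <- trainSizeSVM(man$area_px[trainIdx], labels[trainIdx])
            sc <- decisionValues(model, man$area_px[testIdx])
            epochs <- NA_integer_
        }
        rows[[vi]] <- data.frame(validation = vi, test_dish = dishes[vi],
                                 auc = computeAUC(sc, truthTest),
                                 n_train = length(trainIdx),
                                 n_test = length(testIdx), epochs = epochs)
        rocs[[vi]] <- rocPoints(sc, truthTest)
    }
    new("EvaluationResult", table = DataFrame(do.call(rbind, rows)),
        rocs = rocs,
        config = list(classifier = classifier,
                      channels = if (classifier == "cnn") channels else
                          "area_px",
                      train = if (classifier == "cnn") train else NULL))
}

#' Training-set size sweep with a fixed test set
#'
#' Emulates the learning-curve protocol: the held-out test dish is fixed
#' while training subsets of increasing size are drawn at random (one
#' independent draw per seed) from the remaining dishes.
#'
#' @param cellSet a labelled, balanced \code{\link{CellSet}}.
#' @param sizes training-set sizes (cells); sizes exceeding availability
#'   are clipped with a warning.
#' @param nSeeds number of independent subsample draws per size.
#' @param testDish dish held out as the fixed test set.
#' @param classifier,channels,train,maskRadius as in
#'   \code{\link{crossValidate}}.
#' @param presentationBudget optional fixed training budget in sample
#'   presentations per fit (CNN only): each size trains for
#'   \code{ceiling(presentationBudget / size)} epochs (capped by
#'   \code{train$maxEpochs}), so every fit receives a comparable number of
#'   gradient steps and the sweep isolates the effect of data diversity.
#'   \code{NULL} trains every size with the full \code{train} protocol.
#' @param seed base seed for the subsample draws.
#' @return data.frame (size, seed, auc, n_train, epochs).
#' @export
sizeSweep <- function(cellSet, sizes = c(100L, 300L, 1000L, 3000L),
                      nSeeds = 5L, testDish = NULL,
                      classifier = c("svm", "cnn"), channels = "dic",
                      train = trainSpec(), maskRadius = 50,
                      presentationBudget = NULL, seed = 1L) {
    classifier <- match.arg(classifier)
    man <- manifest(cellSet)
    dishes <- sort(unique(man$dish))
    if (is.null(testDish)) testDish <- dishes[length(dishes)]
    labels <- droplevels(factor(man$label, levels = c("LMPP", "proB")))
    testIdx <- which(man$dish == testDish)
    poolIdx <- which(man$dish != testDish)
    prep <- if (classifier == "cnn")
        prepareInputs(cellSet, channels, radius = maskRadius) else NULL
    out <- list()
    for (sz in sizes) {
        szUse <- sz
        if (szUse > length(poolIdx)) {
            warning(sprintf("size %d clipped to %d available cells", sz,
                            length(poolIdx)))
            szUse <- length(poolIdx)
        }
        for (s in seq_len(nSeeds)) {
            trIdx <- withSeed(subSeed(seed, sz, s),
                              sample(poolIdx, szUse))
            if (nlevels(droplevels(labels[trIdx])) < 2L)
                stop("training subsample has a single class")
            if (classifier == "svm") {
                model <- trainSizeSVM(man$area_px[trIdx], labels[trIdx])
                sc <- decisionValues(model, man$area_px[testIdx])
            } else {
                epochCap <- if (is.null(presentationBudget))
                    train$maxEpochs
                else min(train$maxEpochs,
                         max(1L, as.integer(ceiling(presentationBudget /
                                                    szUse))))
                fold <- trainSpec(alpha = train$alpha,
                                  batchSize = train$batchSize,
                                  valFraction = train$valFraction,
                                  patience = train$patience,
                                  maxEpochs = epochCap,
                                  initSeed = subSeed(train$initSeed, sz, s),
                                  orderSeed = subSeed(train$orderSeed, sz, s),
                                  splitSeed = subSeed(train$splitSeed, sz, s))
                model <- trainCNN(prep$x[, , , trIdx, drop = FALSE],
                                  labels[trIdx], train = fold,
                                  channels = channels)
                sc <- predictProba(model,
                                   prep$x[, , , testIdx,
                                          drop = FALSE])[, "proB"]
            }
            out[[length(out) + 1L]] <-
                data.frame(size = sz, seed = s,
                           auc = computeAUC(sc, labels[testIdx]),
                           n_train = szUse)
        }
    }
    do.call(rbind, out)
}

#' Run a grid of input configurations
#'
#' Evaluates a list of configurations by dish-level cross-validation on
#' the same balanced cell set, so configurations are directly comparable.
#' Each plan entry is a list with \code{name}, \code{classifier}
#' (\code{"cnn"} or \code{"svm"}) and, for the CNN, \code{channels} (crop
#' keys; z/time-plane keys give focal-offset and time-stack
#' configurations). Optional \code{seeds} (vector of init seeds) repeats
#' the CNN fit per seed to measure initialisation variability.
#'
#' @param cellSet a labelled, balanced \code{\link{CellSet}}.
#' @param plan list of configuration entries.
#' @param train base \code{\link{trainSpec}}.
#' @param maskRadius circular-mask radius.
#' @return list: \code{results} (long data.frame: configuration,
#'   validation, test_dish, init_seed, auc), \code{summary}
#'   (per-configuration mean, between-dish sd, between-seed sd).
#' @export
runGrid <- function(cellSet, plan, train = trainSpec(), maskRadius = 50) {
    rows <- list()
    for (entry in plan) {
        seeds <- entry$seeds %||% train$initSeed
        for (sd0 in seeds) {
            tr <- trainSpec(alpha = train$alpha, batchSize = train$batchSize,
                            valFraction = train$valFraction,
                            patience = train$patience,
                            maxEpochs = train$maxEpochs, seed = sd0)
            ev <- crossValidate(cellSet, classifier = entry$classifier,
                                channels = entry$channels %||% "dic",
                                train = tr, maskRadius = maskRadius)
            tab <- as.data.frame(aucTable(ev))
            rows[[length(rows) + 1L]] <-
                data.frame(configuration = entry$name,
                           validation = tab$validation,
                           test_dish = tab$test_dish, init_seed = sd0,
                           auc = tab$auc)
        }
    }
    results <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(results, results$configuration),
        function(d) {
            byDish <- tapply(d$auc, d$test_dish, mean)
            bySeed <- tapply(d$auc, d$init_seed, mean)
            data.frame(configuration = d$configuration[1],
                       mean_auc = mean(d$auc),
                       sd_between_dish = stats::sd(byDish),
                       sd_between_seed = if (length(bySeed) > 1)
                           stats::sd(bySeed) else NA_real_)
        }))
    rownames(summ) <- NULL
    list(results = results, summary = summ)
}

#' Null band for the mean cross-validated AUC
#'
#' Central quantile band of the mean (over validations) AUC under the
#' permutation null of exchangeable scores, at the given test-set class
#' sizes.
#'
#' @param n0s,n1s per-validation negative/positive test counts.
#' @param B number of permutation replicates.
#' @param level central coverage (e.g. 0.99).
#' @param seed RNG seed.
#' @return length-2 vector, the lower and upper band limits.
#' @export
aucNullBand <- function(n0s, n1s, B = 2000L, level = 0.99, seed = 1L) {
    stopifnot(length(n0s) == length(n1s))
    withSeed(seed, {
        means <- vapply(seq_len(B), function(b) {
            mean(vapply(seq_along(n0s), function(d) {
                sc <- stats::runif(n0s[d] + n1s[d])
                computeAUC(sc, c(rep(0, n0s[d]), rep(1, n1s[d])))
            }, 0))
        }, 0)
        stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
    })
}

#' Paired permutation comparison of two configurations
#'
#' Sign-flip permutation test on per-validation AUC differences between
#' two configurations evaluated on the same validations.
#'
#' @param aucsA,aucsB per-validation AUCs of the two configurations.
#' @param B permutation replicates (exhaustive when feasible).
#' @param seed RNG seed.
#' @return list: \code{meanDiff}, \code{pValue} (two-sided).
#' @export
comparePairedAUC <- function(aucsA, aucsB, B = 10000L, seed = 1L) {
    stopifnot(length(aucsA) == length(aucsB))
    d <- aucsA - aucsB
    k <- length(d)
    obs <- mean(d)
    if (k <= 20L) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
        null <- signs %*% d / k
    } else {
        null <- withSeed(seed, vapply(seq_len(B), function(b)
            mean(d * sample(c(-1, 1), k, replace = TRUE)), 0))
    }
    list(meanDiff = obs, pValue = mean(abs(null) >= abs(obs) - 1e-12))
}
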