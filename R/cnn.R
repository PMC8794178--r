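#' Rectified linear unit
#' @param x numeric vector/array.
#' @return elementwise \code{max(x, 0)}.
#' @export
relu <- function(x) pmax(x, 0)

#' Two-class softmax
#'
#' Shift-invariant implementation (the max is subtracted before
#' exponentiation, so large logits cannot overflow).
#' @param x numeric vector of logits.
#' @return probability vector of the same length summing to 1.
#' @export
softmaxProb <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
}

#' Binary cross-entropy loss
#'
#' \code{H(y, yhat) = -y log(yhat) - (1-y) log(1-yhat)}, with \code{yhat}
#' clamped to \code{[clampEps, 1 - clampEps]} for numeric safety; minimal
#' (0) at \code{yhat = y}.
#'
#' @param y 0/1 labels.
#' @param yhat predicted probability of class 1.
#' @param clampEps clamping constant.
#' @return elementwise loss.
#' @export
bceLoss <- function(y, yhat, clampEps = 1e-7) {
    yhat <- pmin(pmax(yhat, clampEps), 1 - clampEps)
    -y * log(yhat) - (1 - y) * log(1 - yhat)
}

#' Early-stopping rule on a validation-loss sequence
#'
#' An epoch is non-improving when its validation loss is not strictly
#' below the minimum of all earlier epochs. Training stops once
#' \code{patience} consecutive trailing epochs are non-improving, or at
#' \code{maxEpochs}; the restored model is the one with the smallest
#' validation loss seen.
#'
#' @param valLosses numeric vector of per-epoch validation losses so far.
#' @param patience consecutive non-improving epochs tolerated.
#' @param maxEpochs hard epoch cap.
#' @return list(\code{stop}, \code{best}): whether to stop now and the
#'   1-based index of the best epoch.
#' @export
earlyStopEpoch <- function(valLosses, patience = 5L, maxEpochs = 30L) {
    e <- length(valLosses)
    best <- which.min(valLosses)
    if (e >= maxEpochs) return(list(stop = TRUE, best = best))
    trailing <- 0L
    for (k in seq_len(e)[-1]) {
        if (valLosses[k] >= min(valLosses[seq_len(k - 1L)]))
            trailing <- trailing + 1L
        else trailing <- 0L
    }
    list(stop = trailing >= patience, best = best)
}

#' CNN architecture specification
#'
#' Four 5x5 same-padded convolution layers with channel widths
#' (16, 16, 32, 32) for single-channel input, doubled to (32, 32, 64, 64)
#' for two or more input channels; ReLU after each convolution, then a
#' 3x3 stride-2 valid max-pool and dropout (rate 0.1) in every gap; a
#' 2000-node fully connected ReLU layer with dropout; a 2-node softmax
#' output. The spatial chain and flatten size are computed (and checked)
#' from the input size rather than assumed.
#'
#' @param nChannels number of stacked input channels.
#' @param inputSize crop edge length (px).
#' @param fcNodes fully connected layer width.
#' @param dropout dropout rate in all gaps.
#' @return list describing the architecture.
#' @export
cnnSpec <- function(nChannels = 1L, inputSize = 150L, fcNodes = 2000L,
                    dropout = 0.1) {
    widths <- c(16L, 16L, 32L, 32L) * (if (nChannels >= 2L) 2L else 1L)
    sizes <- Reduce(function(H, k) (H - 3L) %/% 2L + 1L, seq_len(4),
                    accumulate = TRUE, init = as.integer(inputSize))
    if (any(sizes < 1L))
        stop("input size too small for four pooling stages")
    list(nChannels = as.integer(nChannels), inputSize = as.integer(inputSize),
         widths = widths, kernel = 5L, poolKernel = 3L, poolStride = 2L,
         fcNodes = as.integer(fcNodes), dropout = dropout,
         spatialSizes = sizes,
         flatSize = sizes[5]^2 * widths[4])
}

#' CNN training protocol
#'
#' Adam with the fixed protocol: alpha = 1e-4, beta1 = 0.9, beta2 = 0.999,
#' eps = 1e-8, batch size 32, a stratified 10\% validation split,
#' early-stopping patience 5 on validation loss, epoch cap 30. \code{eta}
#' is recorded for completeness and treated as an identity learning-rate
#' multiplier.
#'
#' @param alpha,beta1,beta2,eps,eta Adam parameters.
#' @param batchSize minibatch size.
#' @param valFraction fraction of training data held out for validation.
#' @param patience,maxEpochs early-stopping parameters.
#' @param seed master seed; the init, data-order and split streams derive
#'   from it (override individually via \code{initSeed}, \code{orderSeed},
#'   \code{splitSeed}).
#' @param initSeed,orderSeed,splitSeed individual stream seeds.
#' @return list describing the training protocol.
#' @export
trainSpec <- function(alpha = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      eta = 1.0, batchSize = 32L, valFraction = 0.1,
                      patience = 5L, maxEpochs = 30L, seed = 1L,
                      initSeed = NULL, orderSeed = NULL, splitSeed = NULL) {
    list(alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps, eta = eta,
         batchSize = as.integer(batchSize), valFraction = valFraction,
         patience = as.integer(patience), maxEpochs = as.integer(maxEpochs),
         initSeed = as.integer(initSeed %||% seed),
         orderSeed = as.integer(orderSeed %||% subSeed(seed, 101L)),
         splitSeed = as.integer(splitSeed %||% subSeed(seed, 202L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## He-normal initialisation of all parameter matrices, in the fixed order
## the C++ engine expects.
initCnnWeights <- function(spec, seed) {
    withSeed(seed, {
        w <- list()
        cin <- spec$nChannels
        for (k in 1:4) {
            cout <- spec$widths[k]
            fanin <- cin * spec$kernel^2
            w[[sprintf("W%d", k)]] <-
                matrix(rnorm(fanin * cout, 0, sqrt(2 / fanin)), fanin, cout)
            w[[sprintf("b%d", k)]] <- numeric(cout)
            cin <- cout
        }
        w$F1 <- matrix(rnorm(spec$flatSize * spec$fcNodes, 0,
                             sqrt(2 / spec$flatSize)),
                       spec$flatSize, spec$fcNodes)
        w$bf1 <- numeric(spec$fcNodes)
        w$F2 <- matrix(rnorm(spec$fcNodes * 2, 0, sqrt(2 / spec$fcNodes)),
                       spec$fcNodes, 2)
        w$bf2 <- numeric(2)
        w
    })
}

dimsVector <- function(spec) {
    as.integer(c(spec$inputSize, spec$nChannels, spec$widths, spec$fcNodes))
}

#' Train the CNN
#'
#' Trains on preprocessed crops with Adam, a stratified validation split,
#' and early stopping; returns the parameter state with the smallest
#' validation loss. Fully reproducible from the seeds in \code{train}.
#'
#' @param x input array \code{size x size x channels x cells} (from
#'   \code{\link{prepareInputs}}).
#' @param y labels: factor with levels LMPP/proB, or 0/1 (1 = proB).
#' @param spec architecture from \code{\link{cnnSpec}} (defaults to the
#'   channel count of \code{x}).
#' @param train protocol from \code{\link{trainSpec}}.
#' @param channels crop-channel keys recorded on the model.
#' @param verbose print per-epoch losses.
#' @return a \code{\link{CNNClassifier}}.
#' @export
trainCNN <- function(x, y, spec = NULL, train = trainSpec(),
                     channels = character(0), verbose = FALSE) {
    stopifnot(length(dim(x)) == 4L)
    y <- encodeLabels(y)
    n <- dim(x)[4]
    stopifnot(length(y) == n)
    if (length(unique(y)) < 2L)
        stop("training set contains a single class")
    if (is.null(spec)) spec <- cnnSpec(nChannels = dim(x)[3],
                                       inputSize = dim(x)[1])
    stopifnot(spec$nChannels == dim(x)[3])
    ## stratified validation split
    valIdx <- withSeed(train$splitSeed, {
        unlist(lapply(split(seq_len(n), y), function(idx)
            sample(idx, max(1L, round(train$valFraction * length(idx))))),
            use.names = FALSE)
    })
    trIdx <- setdiff(seq_len(n), valIdx)
    weights <- initCnnWeights(spec, train$initSeed)
    mState <- list(); vState <- list(); tStep <- 0L
    dims <- dimsVector(spec)
    lr <- train$alpha * train$eta
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(loss = Inf, weights = weights, epoch = 0L)
    valLosses <- numeric(0)
    for (epoch in seq_len(train$maxEpochs)) {
        ord <- withSeed(subSeed(train$orderSeed, epoch),
                        sample(trIdx, length(trIdx)))
        res <- .cnnEpoch(weights, mState, vState, tStep, x, y, ord,
                         train$batchSize, lr, train$beta1, train$beta2,
                         train$eps, spec$dropout,
                         subSeed(train$orderSeed, epoch, 7L), dims)
        weights <- res$weights; mState <- res$m; vState <- res$v
        tStep <- res$t
        pv <- .cnnForward(weights, x[, , , valIdx, drop = FALSE], dims,
                          length(valIdx))
        valLoss <- mean(bceLoss(y[valIdx], pv[, 2]))
        valLosses <- c(valLosses, valLoss)
        history <- rbind(history, data.frame(epoch = epoch,
                                             train_loss = res$trainLoss,
                                             val_loss = valLoss))
        if (verbose)
            message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                            res$trainLoss, valLoss))
        if (valLoss < best$loss)
            best <- list(loss = valLoss, weights = weights, epoch = epoch)
        es <- earlyStopEpoch(valLosses, train$patience, train$maxEpochs)
        if (es$stop) break
    }
    new("CNNClassifier", spec = spec, train = train, weights = best$weights,
        channels = as.character(channels), history = history,
        bestEpoch = best$epoch)
}

encodeLabels <- function(y) {
    if (is.factor(y) || is.character(y)) {
        y <- as.character(y)
        bad <- !y %in% c("LMPP", "proB")
        if (any(bad)) stop("labels must be LMPP/proB")
        as.integer(y == "proB")
    } else {
        stopifnot(all(y %in% c(0, 1)))
        as.integer(y)
    }
}

#' Predict class probabilities with a trained CNN
#'
#' Inference mode (dropout off); deterministic for fixed weights.
#'
#' @param model a \code{\link{CNNClassifier}}.
#' @param x input array \code{size x size x channels x cells}, same channel
#'   configuration as in training.
#' @return matrix \code{n x 2} with columns \code{LMPP}, \code{proB}
#'   (rows sum to 1).
#' @export
predictProba <- function(model, x) {
    stopifnot(is(model, "CNNClassifier"), length(dim(x)) == 4L)
    if (dim(x)[3] != model@spec$nChannels)
        stop(sprintf("channel mismatch: model expects %d, input has %d",
                     model@spec$nChannels, dim(x)[3]))
    p <- .cnnForward(model@weights, x, dimsVector(model@spec), dim(x)[4])
    colnames(p) <- c("LMPP", "proB")
    p
}
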