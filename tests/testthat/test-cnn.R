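test_that("activation, softmax and loss primitives match hand values", {
    expect_equal(relu(-1), 0)
    expect_equal(relu(2.5), 2.5)
    expect_equal(relu(c(-3, 0, 3)), c(0, 0, 3))
    expect_equal(softmaxProb(c(0, 0)), c(0.5, 0.5))
    expect_equal(softmaxProb(c(log(3), 0)), c(0.75, 0.25))
    expect_equal(softmaxProb(c(5, 2) + 1000), softmaxProb(c(5, 2)))
    expect_equal(sum(softmaxProb(c(1e4, -1e4))), 1)   # no overflow
    expect_equal(bceLoss(1, 1), bceLoss(1, 1 - 1e-7))
    expect_lt(bceLoss(1, 1), 1e-6)
    expect_equal(bceLoss(1, 0.5), log(2))
    expect_equal(bceLoss(0, 0.5), log(2))
    expect_equal(bceLoss(c(1, 0), c(0.9, 0.1)), rep(-log(0.9), 2))
})

test_that("early stopping traces the patience rule and restores the best epoch", {
    losses <- c(1.0, 0.9, 0.91, 0.92, 0.93, 0.94, 0.95)
    ## after epoch 6 only 4 non-improving epochs have accrued: continue
    expect_false(earlyStopEpoch(losses[1:6])$stop)
    es <- earlyStopEpoch(losses)
    expect_true(es$stop)
    expect_equal(es$best, 2L)
    ## strictly decreasing losses run to the epoch cap
    dec <- seq(1, 0.1, length.out = 30)
    expect_false(earlyStopEpoch(dec[1:29])$stop)
    es2 <- earlyStopEpoch(dec, maxEpochs = 30L)
    expect_true(es2$stop)
    expect_equal(es2$best, 30L)
})

test_that("architecture spatial chain is computed, not assumed", {
    sp <- cnnSpec(1L)
    expect_equal(sp$spatialSizes, c(150L, 74L, 36L, 17L, 8L))
    expect_equal(sp$widths, c(16L, 16L, 32L, 32L))
    expect_equal(sp$flatSize, 8L^2 * 32L)
    sp2 <- cnnSpec(2L)
    expect_equal(sp2$widths, c(32L, 32L, 64L, 64L))
    expect_equal(sp2$flatSize, 8L^2 * 64L)
    sp3 <- cnnSpec(3L)
    expect_equal(sp3$widths, sp2$widths)
    expect_error(cnnSpec(1L, inputSize = 8L), "too small")
})

test_that("training is deterministic, and inference sums to one", {
    set.seed(77)
    n <- 24
    x <- array(rnorm(150 * 150 * n), c(150, 150, 1, n))
    y <- rep(c(0, 1), n / 2)
    ts <- trainSpec(maxEpochs = 1L, seed = 11L)
    m1 <- trainCNN(x, y, train = ts)
    m2 <- trainCNN(x, y, train = ts)
    expect_identical(m1@weights, m2@weights)
    p <- predictProba(m1, x)
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-5)
    ## duplicated record, identical output
    x2 <- x[, , , c(1, 1), drop = FALSE]
    p2 <- predictProba(m1, x2)
    expect_identical(p2[1, ], p2[2, ])
    ## all-zero crops are tolerated
    p0 <- predictProba(m1, array(0, c(150, 150, 1, 1)))
    expect_equal(sum(p0), 1, tolerance = 1e-5)
    ## different init seed, different parameters
    m3 <- trainCNN(x, y, train = trainSpec(maxEpochs = 1L, seed = 12L))
    expect_false(identical(m3@weights, m1@weights))
})

test_that("training rejects bad inputs and channel mismatches", {
    x <- array(rnorm(150 * 150 * 8), c(150, 150, 1, 8))
    expect_error(trainCNN(x, rep(1, 8),
                          train = trainSpec(maxEpochs = 1L)),
                 "single class")
    m <- trainCNN(x, rep(c(0, 1), 4), train = trainSpec(maxEpochs = 1L))
    x2 <- array(rnorm(150 * 150 * 2 * 2), c(150, 150, 2, 2))
    expect_error(predictProba(m, x2), "channel mismatch")
})

test_that("the returned state has the smallest validation loss seen", {
    set.seed(42)
    n <- 40
    ## separable data so losses move
    y <- rep(c(0, 1), n / 2)
    x <- array(0, c(150, 150, 1, n))
    for (i in seq_len(n))
        x[, , 1, i] <- matrix(rnorm(150^2, mean = y[i] * 0.5), 150, 150)
    m <- trainCNN(x, y, train = trainSpec(maxEpochs = 4L, seed = 3L))
    h <- m@history
    expect_equal(m@bestEpoch, which.min(h$val_loss))
    expect_lte(h$val_loss[m@bestEpoch], h$val_loss[nrow(h)])
})

test_that("the CNN learns a separable size difference", {
    set.seed(6)
    n <- 120
    y <- rep(c(0, 1), n / 2)
    dm <- cellchannel:::discMask(150, 50)
    x <- array(0, c(150, 150, 1, n))
    d2 <- outer((seq_len(150) - 76)^2, (seq_len(150) - 76)^2, "+")
    for (i in seq_len(n)) {
        r <- if (y[i] == 1) 38 else 28
        img <- matrix(1, 150, 150)
        img[d2 < r^2] <- 0.5
        img <- (img + matrix(rnorm(150^2, 0, 0.1), 150, 150)) * dm
        x[, , 1, i] <- img / mean(img[dm])
    }
    m <- trainCNN(x, y, train = trainSpec(maxEpochs = 8L, seed = 2L))
    auc <- computeAUC(predictProba(m, x)[, "proB"], y)
    expect_gt(auc, 0.95)
})
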