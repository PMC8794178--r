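test_that("AUC equals the Mann-Whitney pair statistic on small instances", {
    expect_equal(computeAUC(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
    expect_equal(computeAUC(rep(1, 10), rep(c(0, 1), 5)), 0.5)
    expect_error(computeAUC(1:4, rep(1, 4)), "both classes")
    set.seed(99)
    for (k in 1:30) {
        n <- sample(4:60, 1)
        truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
        scores <- sample(seq_len(max(2, n %/% 3)), n, replace = TRUE)  # ties
        expect_equal(computeAUC(scores, truth), aucPairOracle(scores, truth))
    }
})

test_that("AUC agrees with pROC", {
    skip_if_not_installed("pROC")
    set.seed(5)
    truth <- sample(0:1, 300, replace = TRUE, prob = c(0.4, 0.6))
    scores <- rnorm(300) + truth
    expect_equal(computeAUC(scores, truth),
                 as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                quiet = TRUE))))
})

test_that("dish-level cross-validation holds out each dish once", {
    set.seed(12)
    n <- 300
    dishes <- rep(1:3, each = 100)
    labels <- rep(rep(c("LMPP", "proB"), each = 50), 3)
    areas <- round(rnorm(n, ifelse(labels == "proB", 4200, 3200), 400))
    cs <- tabularCellSet(areas, labels, dishes)
    ev <- crossValidate(cs, classifier = "svm")
    tab <- as.data.frame(aucTable(ev))
    expect_equal(nrow(tab), 3L)
    expect_equal(tab$test_dish, 1:3)
    expect_equal(tab$validation, 1:3)
    expect_equal(tab$n_train, rep(200L, 3))
    expect_true(all(tab$auc >= 0 & tab$auc <= 1))
    ## a strong size effect is detected in every validation
    expect_true(all(tab$auc > 0.8))
    ## ROC curves span (0,0) to (1,1)
    for (roc in ev@rocs) {
        expect_equal(roc$fpr[1], 0)
        expect_equal(roc$tpr[nrow(roc)], 1)
    }
})

test_that("cross-validation refuses single-class test dishes", {
    cs <- tabularCellSet(c(3000, 3100, 4000, 4100),
                         c("LMPP", "LMPP", "proB", "proB"),
                         c(1, 1, 2, 2))
    expect_error(crossValidate(cs, classifier = "svm"), "single class")
})

test_that("size sweep keeps the test set fixed while training sets vary", {
    set.seed(44)
    n <- 900
    dishes <- rep(1:3, each = 300)
    labels <- rep(rep(c("LMPP", "proB"), each = 150), 3)
    areas <- round(rnorm(n, ifelse(labels == "proB", 4100, 3300), 500))
    cs <- tabularCellSet(areas, labels, dishes)
    sw <- sizeSweep(cs, sizes = c(50L, 200L), nSeeds = 3L, testDish = 3L,
                    classifier = "svm", seed = 7L)
    expect_equal(nrow(sw), 6L)
    expect_true(all(sw$n_train == sw$size))
    ## reproducibility: same seed, identical sweep
    sw2 <- sizeSweep(cs, sizes = c(50L, 200L), nSeeds = 3L, testDish = 3L,
                     classifier = "svm", seed = 7L)
    expect_identical(sw, sw2)
    ## requested size beyond availability is clipped with a warning
    expect_warning(sizeSweep(cs, sizes = 5000L, nSeeds = 1L, testDish = 3L,
                             classifier = "svm", seed = 1L), "clipped")
})

test_that("runGrid returns comparable long-format results with summaries", {
    set.seed(13)
    n <- 240
    dishes <- rep(1:3, each = 80)
    labels <- rep(rep(c("LMPP", "proB"), each = 40), 3)
    areas <- round(rnorm(n, ifelse(labels == "proB", 4400, 3000), 350))
    cs <- tabularCellSet(areas, labels, dishes)
    out <- runGrid(cs, plan = list(list(name = "size-SVM",
                                        classifier = "svm")))
    expect_equal(nrow(out$results), 3L)
    expect_named(out$summary,
                 c("configuration", "mean_auc", "sd_between_dish",
                   "sd_between_seed"))
    expect_equal(out$summary$mean_auc, mean(out$results$auc))
})

test_that("null band brackets 0.5 and narrows with test size", {
    b1 <- aucNullBand(rep(50, 3), rep(50, 3), B = 500L, seed = 2L)
    expect_lt(b1[1], 0.5)
    expect_gt(b1[2], 0.5)
    b2 <- aucNullBand(rep(500, 3), rep(500, 3), B = 500L, seed = 2L)
    expect_lt(diff(b2), diff(b1))
})

test_that("paired AUC comparison detects ties and differences", {
    same <- comparePairedAUC(c(0.9, 0.91, 0.89), c(0.9, 0.91, 0.89))
    expect_equal(same$meanDiff, 0)
    expect_equal(same$pValue, 1)
    diffr <- comparePairedAUC(c(0.95, 0.94, 0.96), c(0.60, 0.61, 0.59))
    expect_equal(diffr$meanDiff, 0.35, tolerance = 1e-9)
    expect_lt(diffr$pValue, 0.3)   # exhaustive over 8 sign flips
})
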