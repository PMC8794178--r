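test_that("marker total counts exactly the lattice points within 30 px", {
    ## enumeration oracle: lattice points with dx^2 + dy^2 < 900 around the
    ## centre pixel (76, 76) of a 150-crop
    d2 <- outer((seq_len(150) - 76)^2, (seq_len(150) - 76)^2, "+")
    nIn <- sum(d2 < 900)
    expect_equal(markerTotal(matrix(1, 150, 150)), nIn)
    ## single-pixel mass inside the radius
    crop <- matrix(0, 150, 150)
    crop[76, 81] <- 7      # distance 5
    expect_equal(markerTotal(crop), 7)
    ## outside the radius: excluded
    crop2 <- matrix(0, 150, 150)
    crop2[76, 116] <- 7    # distance 40
    expect_equal(markerTotal(crop2), 0)
})

test_that("log relative intensity follows its definition", {
    expect_equal(logRelativeIntensity(c(1, exp(1))), c(-1, 0))
    expect_equal(logRelativeIntensity(rep(4, 5)), rep(0, 5))
    l <- c(2, 7, 5)
    F <- logRelativeIntensity(l)
    expect_equal(F[which.max(l)], 0)
    expect_true(all(F <= 0))
    expect_error(logRelativeIntensity(numeric(0)), "empty")
    expect_error(logRelativeIntensity(c(1, -1)), "positive")
})

test_that("mixture fit recovers well-separated components and labels", {
    set.seed(11)
    F <- c(rnorm(1000, -4, 0.1), rnorm(1000, -0.5, 0.1))
    fit <- fitLabelGMM(F, seed = 2L)
    expect_true(fit$model@converged)
    expect_lt(abs(fit$model@means[1] - (-4)), 0.05)
    expect_lt(abs(fit$model@means[2] - (-0.5)), 0.05)
    expect_gt(mean(fit$labels != "unused"), 0.99)
    ## labels match the generating component among non-unused cells
    truthLab <- rep(c("LMPP", "proB"), each = 1000)
    ok <- fit$labels != "unused"
    expect_gt(mean(as.character(fit$labels[ok]) == truthLab[ok]), 0.995)
})

test_that("posterior 0.5 is unused, posterior >= 0.8 is labelled", {
    set.seed(5)
    F <- c(rnorm(500, -3, 0.3), rnorm(500, -1, 0.3))
    fit <- fitLabelGMM(F, seed = 1L)
    m <- fit$model
    ## the midpoint of symmetric equal-weight components has posterior ~0.5
    post <- cellchannel:::posteriorProB(F, m@means, m@sds, m@weights)
    expect_true(all(fit$labels[post >= 0.8] == "proB"))
    expect_true(all(fit$labels[post < 0.8 & post > 0.2] == "unused"))
    expect_true(all(fit$labels[(1 - post) >= 0.8] == "LMPP"))
    ## unused interval brackets the low-confidence region between the means
    ui <- unusedInterval(m)
    expect_true(ui[1] > m@means[1] && ui[2] < m@means[2])
    inUI <- F > ui[1] & F < ui[2]
    expect_true(all(fit$labels[inUI] == "unused"))
})

test_that("labels are monotone in F (gating cut points exist)", {
    set.seed(8)
    F <- c(rnorm(400, -3.5, 0.4), rnorm(600, -0.8, 0.5))
    fit <- fitLabelGMM(F, seed = 3L)
    lab <- fit$labels
    fL <- max(F[lab == "LMPP"])
    fB <- min(F[lab == "proB"])
    expect_lt(fL, fB)
    un <- F[lab == "unused"]
    if (length(un)) {
        expect_true(all(un > fL & un < fB))
    }
})

test_that("mixture fit agrees with an independent EM implementation", {
    skip_if_not_installed("mclust")
    suppressMessages(library(mclust))
    set.seed(21)
    F <- c(rnorm(700, -3, 0.5), rnorm(900, -0.7, 0.35))
    fit <- fitLabelGMM(F, seed = 4L)
    mc <- mclust::Mclust(F, G = 2, modelNames = "V", verbose = FALSE)
    ord <- order(mc$parameters$mean)
    expect_equal(fit$model@means,
                 as.numeric(mc$parameters$mean[ord]), tolerance = 0.02)
    expect_equal(fit$model@sds,
                 sqrt(as.numeric(mc$parameters$variance$sigmasq[ord])),
                 tolerance = 0.03)
})

test_that("degenerate inputs error cleanly", {
    expect_error(fitLabelGMM(rep(-1, 50)), "distinct")
})

test_that("labelCells writes the marker statistics into the manifest", {
    fx <- tinyCellSetFixture()
    lab <- labelCells(fx$cellSet, seed = 1L)
    man <- manifest(lab$cellSet)
    expect_true(all(c("l", "F", "posterior_proB", "label") %in%
                    colnames(man)))
    usable <- !is.na(man$F)
    expect_equal(max(man$F[usable]), 0)
    expect_equal(sum(man$F[usable] == 0), 1L)
    ## partition: every usable cell is LMPP, proB or unused
    expect_false(any(is.na(man$label[usable])))
})
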