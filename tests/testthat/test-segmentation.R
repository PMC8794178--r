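test_that("Otsu separates a two-level image and matches hand-checkable cases", {
    img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
    thr <- otsuThreshold(img)
    expect_gt(thr, 10)
    expect_lt(thr, 200)
    ## three values {0, 100, 101} with counts {100, 1, 1}: the split must
    ## isolate the 0s
    img2 <- matrix(c(rep(0, 100), 100, 101), ncol = 1)
    thr2 <- otsuThreshold(img2)
    expect_gt(thr2, 0)
    expect_lt(thr2, 100)
    expect_error(otsuThreshold(matrix(5, 3, 3)), "no threshold")
})

test_that("Otsu equals the exhaustive between-class-variance maximiser", {
    set.seed(42)
    for (k in 1:25) {
        img <- switch(k %% 3 + 1,
            matrix(sample(0:255, 100, replace = TRUE), 10, 10),
            matrix(c(rnorm(60, 40, 10), rnorm(60, 180, 20)), 12, 10),
            matrix(runif(64, 0, 1), 8, 8))
        expect_equal(otsuThreshold(img), otsuBruteForce(img))
    }
})

test_that("Otsu agrees with the EBImage implementation on integer images", {
    set.seed(7)
    img <- matrix(c(rnorm(500, 60, 15), rnorm(500, 190, 20)), 50, 20)
    img <- pmin(pmax(round(img), 0), 255)
    thr <- otsuThreshold(img)
    sc <- (img - min(img)) / (max(img) - min(img))
    thr2 <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1), levels = 256) *
        (max(img) - min(img)) + min(img)
    ## the two formulations may pick different cut points inside the empty
    ## valley; they must induce the same binarisation
    expect_lt(abs(mean(img <= thr) - mean(img <= thr2)), 0.01)
})

test_that("cleaning removes border components, fills holes, closes gaps", {
    ## one component touching the border, one interior
    img <- matrix(100, 60, 60)
    img[1:10, 1:10] <- 10          # touches border
    img[30:40, 30:40] <- 10        # interior 11x11
    fg <- binarizeAndClean(img, 50, closingRadius = 0L)
    expect_false(any(fg[1:10, 1:10]))
    expect_true(all(fg[30:40, 30:40]))
    ## interior hole of 5 px is filled: area grows by exactly 5
    img2 <- matrix(100, 60, 60)
    img2[20:40, 20:40] <- 10
    img2[30, 28:32] <- 100         # 5-px hole
    fg2 <- binarizeAndClean(img2, 50, closingRadius = 0L)
    expect_equal(sum(fg2), 21L * 21L)
    ## closing bridges a 1-px gap: single component afterwards
    img3 <- matrix(100, 60, 60)
    img3[20:40, 20:29] <- 10
    img3[20:40, 31:40] <- 10
    fg3 <- binarizeAndClean(img3, 50, closingRadius = 3L)
    expect_equal(max(EBImage::bwlabel(fg3 * 1)), 1L)
    ## oracle: dilation-then-erosion by the same element bridges it too
    brush <- EBImage::makeBrush(7, "disc")
    closed <- EBImage::erode(EBImage::dilate((img3 <= 50) * 1, brush),
                             brush) > 0
    expect_equal(max(EBImage::bwlabel(closed * 1)), 1L)
    ## empty foreground warns
    expect_warning(binarizeAndClean(matrix(c(100, 200), 10, 10), 50),
                   "empty")
})

test_that("watershed splits overlapping discs and passes singles through", {
    mk <- function(centers, r, d = 200L) {
        m <- matrix(FALSE, d, d)
        for (ct in centers) {
            d2 <- outer((seq_len(d) - ct[1])^2, (seq_len(d) - ct[2])^2, "+")
            m <- m | d2 < r^2
        }
        m
    }
    ## two discs of radius 25 overlapping by 6 px
    m2 <- mk(list(c(100, 80), c(100, 124)), 25)
    reg <- splitTouching(m2)
    expect_equal(nrow(regionTable(reg)), 2L)
    lab <- labelMask(reg)
    expect_true(lab[100, 80] != lab[100, 124])
    expect_true(all(lab[100, 80] > 0, lab[100, 124] > 0))
    ## partition: labels cover exactly the mask
    expect_identical(lab > 0, m2)
    ## single disc: one region, identical to the input
    m1 <- mk(list(c(100, 100)), 25)
    reg1 <- splitTouching(m1)
    expect_equal(nrow(regionTable(reg1)), 1L)
    expect_identical(labelMask(reg1) > 0, m1)
    ## empty mask
    reg0 <- splitTouching(matrix(FALSE, 50, 50))
    expect_equal(nrow(regionTable(reg0)), 0L)
})

test_that("area filter uses strict bounds and relabels consecutively", {
    ## four squares with areas 2000, 2001, 7999, 8000 (as 1-px-wide bars)
    lab <- matrix(0L, 120, 20000)
    lab[10, 1:2000] <- 1L
    lab[30, 1:2001] <- 2L
    lab[50, 1:7999] <- 3L
    lab[70, 1:8000] <- 4L
    regions <- cellchannel:::buildRegionMap(lab)
    filt <- filterByArea(regions, 2000, 8000)
    expect_equal(as.integer(regionTable(filt)$area_px), c(2001L, 7999L))
    expect_equal(regionTable(filt)$label, c(1L, 2L))
    ## empty input passes through
    expect_equal(nrow(regionTable(filterByArea(regions, 1e5, 2e5))), 0L)
})

test_that("pixel areas convert to the printed physical areas", {
    expect_equal(areaToUm2(2000), 52.8125)
    expect_equal(areaToUm2(8000), 211.25)
    ## agreement with the printed figures at their precision (half-ULP of
    ## the last printed digit)
    expect_lte(abs(areaToUm2(2000) - 52.81), 0.005 + 1e-9)
    expect_lte(abs(areaToUm2(8000) - 211.2), 0.05 + 1e-9)
})

test_that("segmented regions partition the cleaned foreground on real fields", {
    fx <- tinyCellSetFixture()
    img <- getChannel(fx$field, "ph")
    fg <- binarizeAndClean(img, otsuThreshold(img))
    reg <- splitTouching(fg)
    lab <- labelMask(reg)
    expect_identical(lab > 0, fg)
    ## region table areas equal mask counts (class validity re-checked)
    expect_true(validObject(reg))
})

test_that("both binarisation polarities work", {
    img <- matrix(100, 50, 50)
    img[20:30, 20:30] <- 10
    expect_true(all(binarizeAndClean(img, 50, "dark",
                                     closingRadius = 0L)[20:30, 20:30]))
    imgB <- 110 - img
    expect_true(all(binarizeAndClean(imgB, 60, "bright",
                                     closingRadius = 0L)[20:30, 20:30]))
})
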