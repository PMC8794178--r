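test_that("crop windows follow the half-open centroid convention", {
    ## a region whose centroid is at 0-based (200, 300) must be cropped
    ## from rows 125..274 and cols 225..374 (0-based, half-open)
    lab <- matrix(0L, 500, 500)
    lab[201, 301] <- 1L                      # 1-based pixel = 0-based (200,300)
    fx <- tinyCellSetFixture()
    half <- 75L
    r <- 201L; c <- 301L
    rows <- (r - half):(r + half - 1L)
    expect_equal(range(rows) - 1L, c(125L, 274L))
    cols <- (c - half):(c + half - 1L)
    expect_equal(range(cols) - 1L, c(225L, 374L))
})

test_that("crops paste back into the field exactly", {
    fx <- tinyCellSetFixture()
    cs <- fx$cellSet
    man <- manifest(cs)
    ph <- getChannel(fx$field, "ph")
    for (i in c(1L, nrow(man))) {
        r <- man$cy[i]; c <- man$cx[i]
        win <- ph[(r - 75):(r + 74), (c - 75):(c + 74)]
        expect_identical(win * 1.0, crops(cs, "ph")[, , i])
    }
})

test_that("contour crops contain only the generating region", {
    fx <- tinyCellSetFixture()
    cs <- fx$cellSet
    man <- manifest(cs)
    lab <- labelMask(fx$regions)
    for (i in seq_len(min(5L, nrow(man)))) {
        cc <- crops(cs, "contour")[, , i]
        expect_lte(sum(cc), man$area_px[i])
        r <- man$cy[i]; c <- man$cx[i]
        win <- lab[(r - 75):(r + 74), (c - 75):(c + 74)]
        expect_identical(cc > 0, win == man$cell_id[i])
    }
    ## full-field region count equals area_px when the region fits the crop
    inWindow <- vapply(seq_len(nrow(man)), function(i)
        sum(crops(cs, "contour")[, , i]) == man$area_px[i], TRUE)
    expect_true(all(inWindow))
})

test_that("near-border cells are skipped, not padded", {
    lab <- matrix(0L, 300, 300)
    lab[5:15, 5:15] <- 1L              # centroid ~10 px from the border
    lab[150:160, 150:160] <- 2L
    regions <- cellchannel:::buildRegionMap(lab)
    fx <- tinyCellSetFixture()
    field <- new("FieldImage",
                 channels = list(ph = array(100, c(300, 300, 1)),
                                 marker = array(100, c(300, 300, 1))),
                 dish = 1L, field = 1L, focalOffsets = 0,
                 timeIndices = 1L, pixelSize = 162.5)
    cs <- cropCells(field, regions, channels = "ph", flattenSigma = NULL)
    expect_equal(nrow(manifest(cs)), 1L)
    expect_equal(attr(cs, "skipped"), 1L)
})

test_that("flat-field correction divides out smooth structure", {
    ## constant image -> constant ~1
    img <- matrix(500, 300, 300)
    fl <- flattenMarkerChannel(img, sigma = 50)
    expect_equal(mean(fl), 1, tolerance = 1e-6)
    expect_lt(max(abs(fl - 1)), 1e-3)
    ## all-zero image -> divisor at floor
    expect_error(flattenMarkerChannel(matrix(0, 50, 50)), "floor")
})

test_that("per-cell flattened totals are invariant to background rescaling", {
    base <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                            fieldShape = c(900L, 900L), cellsPerField = 15L,
                            touchingFraction = 0, noiseSd = 0,
                            backgroundAmplitude = 0.05, seed = 55L)
    fw1 <- generateField(base, 1L, 1L)
    cfg2 <- base
    cfg2$backgroundAmplitude <- 0.1          # same cells, doubled amplitude
    fw2 <- generateField(cfg2, 1L, 1L)
    expect_identical(as.data.frame(cells(fw1$truth)),
                     as.data.frame(cells(fw2$truth)))
    ## cells whose 150-px window stays inside the field
    tc <- as.data.frame(cells(fw1$truth))
    inner <- which(round(tc$cy) > 75 & round(tc$cy) <= 900 - 75 &
                   round(tc$cx) > 75 & round(tc$cx) <= 900 - 75)
    totals <- function(fw) {
        fl <- flattenMarkerChannel(getChannel(fw$field, "marker") * 1.0)
        vapply(inner, function(i) {
            r <- round(tc$cy[i]); c <- round(tc$cx[i])
            markerTotal(fl[(r - 75):(r + 74), (c - 75):(c + 74)])
        }, 0)
    }
    t1 <- totals(fw1); t2 <- totals(fw2)
    expect_gt(length(t1), 5)
    expect_lt(max(abs(t2 / t1 - 1)), 0.05)
})

test_that("flattening an already-flat field is nearly idempotent", {
    ## the property presumes the blur window is background-dominated; with
    ## bright sparse spots the second division shifts totals by the local
    ## cell-light fraction, so test in the dim-marker regime
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                           fieldShape = c(900L, 900L), cellsPerField = 15L,
                           touchingFraction = 0, markerBase = log(5e3),
                           markerBackground = 200,
                           backgroundAmplitude = 0, seed = 58L)
    fw <- generateField(cfg, 1L, 1L)
    mimg <- getChannel(fw$field, "marker") * 1.0
    f1 <- flattenMarkerChannel(mimg)
    f2 <- flattenMarkerChannel(f1)
    tc <- as.data.frame(cells(fw$truth))
    inner <- which(round(tc$cy) > 75 & round(tc$cy) <= 900 - 75 &
                   round(tc$cx) > 75 & round(tc$cx) <= 900 - 75)
    expect_gt(length(inner), 5)
    for (i in inner) {
        r <- round(tc$cy[i]); c <- round(tc$cx[i])
        l1 <- markerTotal(f1[(r - 75):(r + 74), (c - 75):(c + 74)])
        l2 <- markerTotal(f2[(r - 75):(r + 74), (c - 75):(c + 74)])
        expect_lt(abs(l2 / l1 - 1), 0.01)
    }
})

test_that("combineCellSets concatenates crops and keeps ids unique", {
    fx <- tinyCellSetFixture()
    cs <- fx$cellSet
    comb <- combineCellSets(list(cs, cs))
    expect_equal(length(comb), 2L * length(cs))
    expect_false(any(duplicated(manifest(comb)$cell_id)))
    expect_identical(crops(comb, "ph")[, , 1], crops(cs, "ph")[, , 1])
})
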