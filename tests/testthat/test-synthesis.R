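test_that("empty configuration yields a background-only field", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                           fieldShape = c(300L, 300L), cellsPerField = 0L,
                           seed = 3L)
    fw <- generateField(cfg, 1L, 1L)
    expect_equal(nrow(cells(fw$truth)), 0L)
    expect_true(all(labelMask(fw$truth) == 0L))
    ph <- getChannel(fw$field, "ph")
    expect_true(all(is.finite(ph)))
    ## background plus noise only: no pixel far below the background level
    expect_gt(min(ph), 1500)
})

test_that("generation is deterministic and mask ids match ground truth", {
    fw1 <- tinyFieldFixture()
    cfg <- fw1$config
    fw2 <- generateField(cfg, 1L, 1L)
    expect_identical(fw1$field@channels, fw2$field@channels)
    expect_identical(as.data.frame(cells(fw1$truth)),
                     as.data.frame(cells(fw2$truth)))
    ## bijection between mask labels and cell ids
    ids <- sort(unique(as.vector(labelMask(fw1$truth))))
    expect_identical(ids[ids != 0], cells(fw1$truth)$cell_id)
})

test_that("non-touching cells form one connected component each with exact areas", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                           fieldShape = c(1200L, 1200L), cellsPerField = 50L,
                           touchingFraction = 0, seed = 21L)
    fw <- generateField(cfg, 1L, 1L)
    msk <- labelMask(fw$truth)
    ## flood-fill oracle: EBImage connected components of the binary mask
    comp <- EBImage::bwlabel((msk > 0) * 1)
    expect_equal(max(comp), 50L)
    tc <- cells(fw$truth)
    cnt <- tabulate(match(msk[msk > 0], tc$cell_id), nbins = nrow(tc))
    expect_equal(as.integer(tc$area_px), cnt)
})

test_that("experiment bookkeeping: fields, cells, dish effects, reproducibility", {
    cfg <- syntheticConfig(nDishes = 3L, fieldsPerDish = 2L,
                           fieldShape = c(1200L, 1200L), cellsPerField = 50L,
                           seed = 9L)
    ex1 <- generateExperiment(cfg, render = FALSE)
    expect_length(ex1, 6L)
    tot <- sum(vapply(ex1, function(e) nrow(cells(e$truth)), 0L))
    expect_equal(tot, 300L)
    ## cell ids unique across the experiment
    allIds <- unlist(lapply(ex1, function(e) cells(e$truth)$cell_id))
    expect_false(any(duplicated(allIds)))
    ## same seed, same experiment
    ex2 <- generateExperiment(cfg, render = FALSE)
    expect_identical(lapply(ex1, function(e) as.data.frame(cells(e$truth))),
                     lapply(ex2, function(e) as.data.frame(cells(e$truth))))
    ## one illumination gain per dish
    de <- attr(ex1, "dishEffects")
    expect_length(de, 3L)
    expect_length(unique(vapply(de, `[[`, 0, "illumGain")), 3L)
})

test_that("log marker totals separate by the configured amount", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 2L,
                           fieldShape = c(2000L, 2000L),
                           cellsPerField = 300L, markerSeparation = 6,
                           markerSd = 1, seed = 33L)
    ex <- generateExperiment(cfg, render = FALSE)
    tc <- do.call(rbind, lapply(ex, function(e) as.data.frame(cells(e$truth))))
    lt <- log(tc$marker_total)
    mA <- mean(lt[tc$type == "LMPP"]); mB <- mean(lt[tc$type == "proB"])
    sdP <- sqrt(mean(c(var(lt[tc$type == "LMPP"]),
                       var(lt[tc$type == "proB"]))))
    expect_equal((mB - mA) / sdP, 6, tolerance = 0.1)
})

test_that("type frequencies follow the configured fraction", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 4L,
                           fieldShape = c(1500L, 1500L), cellsPerField = 100L,
                           typeFraction = 0.5, seed = 13L)
    ex <- generateExperiment(cfg, render = FALSE)
    tc <- do.call(rbind, lapply(ex, function(e) as.data.frame(cells(e$truth))))
    nB <- sum(tc$type == "proB")
    ## binomial sampling band (4 sd)
    expect_lt(abs(nB - 200), 4 * sqrt(400 * 0.25))
})

test_that("null effects make per-cell statistics exchangeable between types", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                           fieldShape = c(1500L, 1500L), cellsPerField = 120L,
                           sizeMeans = c(3600, 3600), textureEffect = 0,
                           markerSeparation = 0, touchingFraction = 0,
                           seed = 17L)
    fw <- generateField(cfg, 1L, 1L)
    tc <- as.data.frame(cells(fw$truth))
    ## area and marker totals carry no type information: permutation test
    ## on the mean difference
    for (col in c("area_px", "marker_total")) {
        obs <- abs(mean(tc[[col]][tc$type == "proB"]) -
                   mean(tc[[col]][tc$type == "LMPP"]))
        null <- withr::with_seed(1, vapply(1:500, function(b) {
            ty <- sample(tc$type)
            abs(mean(tc[[col]][ty == "proB"]) - mean(tc[[col]][ty == "LMPP"]))
        }, 0))
        expect_gt(mean(null >= obs), 0.01)
    }
})

test_that("overcrowded placement fails with an informative error", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                           fieldShape = c(300L, 300L), cellsPerField = 50L,
                           seed = 1L)
    expect_error(generateField(cfg, 1L, 1L), "dense")
})

test_that("focal planes blur progressively and time planes differ only by noise", {
    cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                           fieldShape = c(700L, 700L), cellsPerField = 10L,
                           nFocalPlanes = 3L, nTimePlanes = 2L, seed = 19L)
    fw <- generateField(cfg, 1L, 1L)
    f <- fw$field
    expect_length(f@focalOffsets, 3L)
    expect_true(0 %in% f@focalOffsets)
    expect_equal(dim(f@channels[["ph"]])[3], 6L)
    refPlane <- which(f@focalOffsets == 0)
    offPlane <- which.max(abs(f@focalOffsets))
    ph <- f@channels[["ph"]]
    ## defocus reduces local contrast
    expect_lt(sd(ph[, , (offPlane - 1) * 2 + 1]),
              sd(ph[, , (refPlane - 1) * 2 + 1]))
    ## time repeats: same signal, independent noise
    d <- ph[, , (refPlane - 1) * 2 + 1] - ph[, , (refPlane - 1) * 2 + 2]
    expect_lt(sd(d), 3 * cfg$noiseSd)
    expect_gt(sd(d), 0.5 * cfg$noiseSd)
})
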