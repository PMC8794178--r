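## Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
    if (!exists(name, envir = .fixtures)) {
        assign(name, force(expr), envir = .fixtures)
    }
    get(name, envir = .fixtures)
}

## One small rendered field with known ground truth (25 well-separated
## cells), reused by segmentation / cropping / labelling tests.
tinyFieldFixture <- function() {
    memo("tinyField", {
        cfg <- syntheticConfig(nDishes = 1L, fieldsPerDish = 1L,
                               fieldShape = c(900L, 900L),
                               cellsPerField = 25L, touchingFraction = 0,
                               seed = 7L)
        fw <- generateField(cfg, 1L, 1L)
        fw$config <- cfg
        fw
    })
}

## Segmentation + crops of the tiny field.
tinyCellSetFixture <- function() {
    memo("tinyCellSet", {
        fw <- tinyFieldFixture()
        regions <- segmentField(fw$field)
        cs <- cropCells(fw$field, regions)
        list(regions = regions, cellSet = cs, truth = fw$truth,
             field = fw$field)
    })
}

## Brute-force AUC over all positive-negative pairs (ties count half).
aucPairOracle <- function(scores, truth) {
    pos <- scores[truth == 1]
    neg <- scores[truth != 1]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

## Exhaustive Otsu: try every interior bin edge of the 256-bin histogram
## and split the raw pixels there; maximise between-class variance.
otsuBruteForce <- function(image, levels = 256L) {
    x <- as.vector(image)
    edges <- seq(min(x), max(x), length.out = levels + 1L)
    cand <- edges[2:levels]
    best <- -Inf; bestT <- cand[1]
    for (t in cand) {
        lo <- x[x <= t]; hi <- x[x > t]
        if (!length(lo) || !length(hi)) next
        w0 <- length(lo) / length(x)
        bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
        if (bcv > best + 1e-12) { best <- bcv; bestT <- t }
    }
    bestT
}

## IoU of each ground-truth cell against its best-overlapping region.
truthRegionIoU <- function(truth, regions) {
    gt <- labelMask(truth)
    sg <- labelMask(regions)
    tc <- cells(truth)
    vapply(seq_len(nrow(tc)), function(i) {
        tpx <- which(gt == tc$cell_id[i])
        if (!length(tpx)) return(0)
        cand <- sg[tpx]
        cand <- cand[cand > 0]
        if (!length(cand)) return(0)
        lab <- as.integer(names(which.max(table(cand))))
        spx <- which(sg == lab)
        length(intersect(tpx, spx)) / length(union(tpx, spx))
    }, 0)
}

## The segmented-region label that covers the majority of a truth cell.
majoritySegLabel <- function(truthMask, segMask, cellId) {
    v <- segMask[truthMask == cellId]
    v <- v[v > 0]
    if (!length(v)) return(NA_integer_)
    as.integer(names(which.max(table(v))))
}

## A minimal CellSet carrying only tabular information (areas, labels),
## for classifier paths that never touch pixel crops.
tabularCellSet <- function(areas, labels, dishes, trueType = NULL) {
    n <- length(areas)
    man <- S4Vectors::DataFrame(
        cell_id = seq_len(n), dish = as.integer(dishes),
        field = rep(1L, n), cx = rep(0, n), cy = rep(0, n),
        area_px = as.integer(areas),
        label = factor(labels, levels = c("LMPP", "proB", "unused")))
    if (!is.null(trueType)) man$true_type <- trueType
    new("CellSet", crops = list(), manifest = man, cropSize = 150L)
}
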