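#' Synthetic experiment configuration
#'
#' Builds the parameter set for the synthetic microscopy generator. The
#' generator emulates dishes of mixed LMPP / pro-B cells imaged in four
#' channels: a phase-contrast-like segmentation channel (\code{"ph"}, dark
#' cell body with a bright halo), two auxiliary transmitted-light channels
#' (\code{"dic"}, \code{"bf"}) and a fluorescence marker channel
#' (\code{"marker"}) whose per-cell total intensity is log-normal and
#' bimodal across the two types. Defaults describe the emulated acquisition:
#' three dishes, 48 fields per dish, a 410 x 346 um field at 162.5 nm/px
#' (2523 x 2129 px) holding ~437 cells mixed 1:1.
#'
#' @param nDishes,fieldsPerDish,cellsPerField experiment layout counts.
#' @param fieldShape integer (height, width) of a field in pixels.
#' @param typeFraction fraction of cells of the marker-positive ("proB")
#'   type.
#' @param sizeMeans length-2 mean pixel areas for (LMPP, proB).
#' @param sizeSd pixel-area standard deviation (shared).
#' @param textureEffect dimensionless effect size >= 0; the proB texture
#'   standard deviation is \code{(1 + textureEffect)} times the LMPP one in
#'   every transmitted-light channel.
#' @param markerSeparation distance between the two types' log marker-total
#'   means (natural-log units).
#' @param markerSd standard deviation of the per-cell log marker total.
#' @param touchingFraction fraction of cells placed as touching pairs.
#' @param touchOverlap pixels by which touching pair members overlap.
#' @param backgroundAmplitude relative amplitude of the smooth illumination
#'   field (0 = flat).
#' @param dishIllumSd standard deviation of the per-dish illumination gain.
#' @param noiseSd additive sensor noise standard deviation (16-bit counts).
#' @param nFocalPlanes number of z-planes; offsets are spread over the
#'   -3.6..+2.7 um range (step grid of the emulated stage) and always
#'   include the in-focus reference 0.
#' @param nTimePlanes number of noise-independent repeat acquisitions.
#' @param seed base RNG seed; all dish/field/cell streams derive from it.
#' @param pixelSize physical pixel size in nanometres.
#' @param bgLevel background intensity of transmitted-light channels
#'   (16-bit counts).
#' @param textureBaseSd LMPP texture standard deviation (16-bit counts).
#' @param markerBase log of the LMPP-type mean marker total.
#' @param markerBackground marker-channel background level (16-bit counts).
#' @param blurPerUm defocus blur sigma in pixels per micrometre of focal
#'   offset.
#' @return a validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nDishes = 3L, fieldsPerDish = 48L,
                            fieldShape = c(2129L, 2523L),
                            cellsPerField = 437L, typeFraction = 0.5,
                            sizeMeans = c(3200, 4000), sizeSd = 600,
                            textureEffect = 0.5, markerSeparation = 3.0,
                            markerSd = 0.5, touchingFraction = 0.1,
                            touchOverlap = 6, backgroundAmplitude = 0.05,
                            dishIllumSd = 0.05, noiseSd = 80,
                            nFocalPlanes = 1L, nTimePlanes = 1L, seed = 1L,
                            pixelSize = 162.5, bgLevel = 3000,
                            textureBaseSd = 200, markerBase = log(4e5),
                            markerBackground = 50, blurPerUm = 2.5) {
    cfg <- list(nDishes = as.integer(nDishes),
                fieldsPerDish = as.integer(fieldsPerDish),
                fieldShape = as.integer(fieldShape),
                cellsPerField = as.integer(cellsPerField),
                typeFraction = typeFraction, sizeMeans = sizeMeans,
                sizeSd = sizeSd, textureEffect = textureEffect,
                markerSeparation = markerSeparation, markerSd = markerSd,
                touchingFraction = touchingFraction,
                touchOverlap = touchOverlap,
                backgroundAmplitude = backgroundAmplitude,
                dishIllumSd = dishIllumSd, noiseSd = noiseSd,
                nFocalPlanes = as.integer(nFocalPlanes),
                nTimePlanes = as.integer(nTimePlanes),
                seed = as.integer(seed), pixelSize = pixelSize,
                bgLevel = bgLevel, textureBaseSd = textureBaseSd,
                markerBase = markerBase,
                markerBackground = markerBackground, blurPerUm = blurPerUm)
    class(cfg) <- "SyntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

validateSyntheticConfig <- function(cfg) {
    stopifnot(isCount(cfg$nDishes), isCount(cfg$fieldsPerDish),
              isCount(cfg$cellsPerField), isCount(cfg$nFocalPlanes),
              isCount(cfg$nTimePlanes),
              cfg$nFocalPlanes >= 1L, cfg$nTimePlanes >= 1L,
              length(cfg$fieldShape) == 2L, all(cfg$fieldShape >= 1L))
    if (cfg$typeFraction < 0 || cfg$typeFraction > 1)
        stop("typeFraction must lie in [0, 1]")
    if (cfg$touchingFraction < 0 || cfg$touchingFraction > 1)
        stop("touchingFraction must lie in [0, 1]")
    if (cfg$sizeSd < 0 || cfg$markerSd < 0 || cfg$noiseSd < 0 ||
        cfg$dishIllumSd < 0)
        stop("standard deviations must be >= 0")
    if (cfg$textureEffect < 0) stop("textureEffect must be >= 0")
    if (length(cfg$sizeMeans) != 2L || any(cfg$sizeMeans <= 0))
        stop("sizeMeans must be two positive pixel areas")
    invisible(TRUE)
}

## Focal offsets (micrometres) for a plane count: evenly spread over the
## emulated -3.6..+2.7 stage range, snapped so the reference 0 is present.
focalOffsetsFor <- function(nFocalPlanes) {
    if (nFocalPlanes == 1L) return(0)
    off <- seq(-3.6, 2.7, length.out = nFocalPlanes)
    off[which.min(abs(off))] <- 0
    off
}

## -- cell placement ---------------------------------------------------------

## Sample per-cell geometry and positions under the non-overlap constraint.
## Touching pairs are placed as rigid units whose members overlap by
## `touchOverlap` pixels along the centre line.
placeCells <- function(cfg) {
    n <- cfg$cellsPerField
    h <- cfg$fieldShape[1]; w <- cfg$fieldShape[2]
    if (n == 0L)
        return(data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                          b = numeric(0), theta = numeric(0),
                          type = character(0), stringsAsFactors = FALSE))
    if (n * mean(cfg$sizeMeans) > 0.45 * h * w)
        stop(sprintf(paste0("field %d x %d too dense for %d cells of mean ",
                            "area %.0f px"), h, w, n, mean(cfg$sizeMeans)))
    nB <- rbinom(1L, n, cfg$typeFraction)
    type <- sample(c(rep("proB", nB), rep("LMPP", n - nB)))
    area <- pmax(rnorm(n, cfg$sizeMeans[ifelse(type == "proB", 2L, 1L)],
                       cfg$sizeSd), 400)
    r <- sqrt(area / pi)
    q <- runif(n, 0.85, 1)
    a <- r / sqrt(q); b <- r * sqrt(q)
    theta <- runif(n, 0, pi)
    nPair <- floor(cfg$touchingFraction * n / 2)
    pairMate <- rep(NA_integer_, n)
    if (nPair > 0)
        for (k in seq_len(nPair)) pairMate[2 * k - 1] <- 2 * k

    cx <- cy <- rep(NA_real_, n)
    placed <- integer(0)
    margin <- pmax(a, b) + 4
    ok <- function(i, x, y) {
        if (x < margin[i] + 1 || x > w - margin[i] ||
            y < margin[i] + 1 || y > h - margin[i]) return(FALSE)
        if (length(placed)) {
            d <- sqrt((cx[placed] - x)^2 + (cy[placed] - y)^2)
            lim <- sqrt(a[i] * b[i]) + sqrt(a[placed] * b[placed]) + 4
            if (any(d < lim)) return(FALSE)
        }
        TRUE
    }
    i <- 1L
    while (i <= n) {
        j <- pairMate[i]
        done <- FALSE
        for (try in seq_len(200L)) {
            x <- runif(1, 1, w); y <- runif(1, 1, h)
            if (!is.na(j)) {
                ang <- runif(1, 0, 2 * pi)
                d <- sqrt(a[i] * b[i]) + sqrt(a[j] * b[j]) - cfg$touchOverlap
                x2 <- x + d * cos(ang); y2 <- y + d * sin(ang)
                if (ok(i, x, y) && ok(j, x2, y2)) {
                    cx[i] <- x; cy[i] <- y; cx[j] <- x2; cy[j] <- y2
                    placed <- c(placed, i, j)
                    done <- TRUE; break
                }
            } else if (ok(i, x, y)) {
                cx[i] <- x; cy[i] <- y
                placed <- c(placed, i)
                done <- TRUE; break
            }
        }
        if (!done)
            stop(sprintf(paste0("cell placement failed (cell %d of %d, ",
                                "density %.2f); reduce cellsPerField or ",
                                "enlarge the field"), i, n,
                         n * mean(cfg$sizeMeans) / (h * w)))
        i <- i + (if (!is.na(j)) 2L else 1L)
    }
    data.frame(cx = cx, cy = cy, a = a, b = b, theta = theta, type = type,
               stringsAsFactors = FALSE)
}

## Rasterise ellipses into an integer label mask. Contested pixels (touching
## pairs) go to the cell whose normalised ellipse metric is smaller, so the
## mask partitions the union of bodies.
rasterizeCells <- function(cellDf, shape, ids) {
    h <- shape[1]; w <- shape[2]
    mask <- matrix(0L, h, w)
    mval <- matrix(Inf, h, w)
    for (i in seq_len(nrow(cellDf))) {
        ai <- cellDf$a[i]; bi <- cellDf$b[i]; th <- cellDf$theta[i]
        ext <- ceiling(max(ai, bi)) + 1L
        r0 <- max(1L, floor(cellDf$cy[i]) - ext)
        r1 <- min(h, ceiling(cellDf$cy[i]) + ext)
        c0 <- max(1L, floor(cellDf$cx[i]) - ext)
        c1 <- min(w, ceiling(cellDf$cx[i]) + ext)
        rr <- r0:r1; cc <- c0:c1
        dy <- matrix(rr - cellDf$cy[i], length(rr), length(cc))
        dx <- matrix(cc - cellDf$cx[i], length(rr), length(cc), byrow = TRUE)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        m <- (u / ai)^2 + (v / bi)^2
        sub <- mask[rr, cc, drop = FALSE]
        sv <- mval[rr, cc, drop = FALSE]
        hit <- m <= 1 & m < sv
        sub[hit] <- ids[i]
        sv[hit] <- m[hit]
        mask[rr, cc] <- sub
        mval[rr, cc] <- sv
    }
    mask
}

## Smooth multiplicative illumination field: mean ~1, relative amplitude
## `amp`, built from two low-frequency sinusoids with random phase and
## orientation (cheap, smooth, seed-reproducible).
illuminationField <- function(shape, amp) {
    h <- shape[1]; w <- shape[2]
    y <- seq_len(h) / h; x <- seq_len(w) / w
    f <- function() {
        fx <- runif(1, 0.4, 1.2); fy <- runif(1, 0.4, 1.2)
        ph <- runif(1, 0, 2 * pi)
        outer(y, x, function(yy, xx) sin(2 * pi * (fx * xx + fy * yy) + ph))
    }
    1 + amp * (f() + f()) / 2
}

## Band-passed per-cell texture: white noise band-passed (difference of
## Gaussians), normalised to unit sd, then scaled inside each body by the
## type's texture sd.
textureLayer <- function(shape, sdMap) {
    wn <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    bp <- EBImage::gblur(wn, sigma = 1.5) - EBImage::gblur(wn, sigma = 4)
    bp <- bp / sd(bp)
    bp * sdMap
}

#' Generate one synthetic multi-channel field
#'
#' Renders one field of view plus its per-cell ground truth. See
#' \code{\link{syntheticConfig}} for the generative model. All randomness
#' derives deterministically from \code{config$seed} and the
#' (\code{dish}, \code{field}) indices, so repeated calls are bit-identical.
#'
#' @param config a \code{SyntheticConfig}.
#' @param dish,field integer identifiers of the field being generated.
#' @param dishEffects optional list of per-dish effects as drawn by
#'   \code{\link{generateExperiment}} (element \code{illumGain}); when
#'   \code{NULL} the dish's own stream draws it.
#' @param idOffset integer added to within-field cell indices to keep cell
#'   ids unique across an experiment.
#' @param render if \code{FALSE}, skip channel rendering and return only the
#'   ground truth (cheap path for experiments that need cell geometry and
#'   marker totals but no pixels).
#' @return a list with elements \code{field} (a \code{\link{FieldImage}}, or
#'   \code{NULL} when \code{render = FALSE}) and \code{truth}
#'   (a \code{\link{GroundTruth}}).
#' @export
generateField <- function(config, dish = 1L, field = 1L, dishEffects = NULL,
                          idOffset = 0L, render = TRUE) {
    validateSyntheticConfig(config)
    cfg <- config
    h <- cfg$fieldShape[1]; w <- cfg$fieldShape[2]
    if (is.null(dishEffects))
        dishEffects <- withSeed(subSeed(cfg$seed, dish, 0L, 990L),
                                list(illumGain = exp(rnorm(1, 0,
                                                           cfg$dishIllumSd))))
    res <- withSeed(subSeed(cfg$seed, dish, field, 1L), {
        cellDf <- placeCells(cfg)
        n <- nrow(cellDf)
        ids <- idOffset + seq_len(n)
        mask <- rasterizeCells(cellDf, cfg$fieldShape, ids)
        areaPx <- if (n) as.integer(tabulate(match(mask[mask > 0L], ids),
                                             nbins = n)) else integer(0)
        markerTotalTrue <- if (n)
            exp(cfg$markerBase +
                cfg$markerSeparation * (cellDf$type == "proB") +
                cfg$markerSd * rnorm(n)) else numeric(0)
        list(cellDf = cellDf, ids = ids, mask = mask, areaPx = areaPx,
             markerTotalTrue = markerTotalTrue)
    })
    cellDf <- res$cellDf
    n <- nrow(cellDf)
    truthCells <- DataFrame(cell_id = res$ids,
                            dish = rep(as.integer(dish), n),
                            field = rep(as.integer(field), n),
                            cx = cellDf$cx, cy = cellDf$cy,
                            type = cellDf$type, area_px = res$areaPx,
                            marker_total = res$markerTotalTrue)
    truth <- new("GroundTruth", cells = truthCells, mask = res$mask)
    if (!render) return(list(field = NULL, truth = truth))

    fimg <- withSeed(subSeed(cfg$seed, dish, field, 2L),
                     renderField(cfg, cellDf, res, dishEffects, dish, field))
    list(field = fimg, truth = truth)
}

## Channel rendering given placed cells. Runs inside a withSeed stream.
renderField <- function(cfg, cellDf, res, dishEffects, dish, field) {
    h <- cfg$fieldShape[1]; w <- cfg$fieldShape[2]
    n <- nrow(cellDf)
    body <- res$mask > 0L
    ## bright phase-contrast halo: 2-px rim just outside the body
    rim <- if (any(body)) {
        EBImage::dilate(body * 1, EBImage::makeBrush(5, "disc")) > 0 & !body
    } else matrix(FALSE, h, w)
    illum <- illuminationField(cfg$fieldShape, cfg$backgroundAmplitude) *
        dishEffects$illumGain
    typeOf <- rep("", n); typeOf[match(res$ids, res$ids)] <- cellDf$type
    texSd <- matrix(0, h, w)
    if (n) {
        sdByCell <- cfg$textureBaseSd *
            (1 + cfg$textureEffect * (cellDf$type == "proB"))
        idx <- res$mask > 0L
        texSd[idx] <- sdByCell[match(res$mask[idx], res$ids)]
    }
    ## level factors per channel: background, body, rim multipliers of bgLevel
    levels <- list(ph = c(1, 0.55, 1.6), dic = c(1, 1.12, 1),
                   bf = c(1, 0.9, 1))
    base <- list()
    for (ch in names(levels)) {
        lv <- matrix(cfg$bgLevel * levels[[ch]][1], h, w)
        lv[body] <- cfg$bgLevel * levels[[ch]][2]
        lv[rim] <- cfg$bgLevel * levels[[ch]][3]
        tex <- if (n && cfg$textureBaseSd > 0) textureLayer(cfg$fieldShape,
                                                            texSd)
               else matrix(0, h, w)
        base[[ch]] <- lv * illum + tex
    }
    ## marker: per-cell Gaussian blob carrying the true total, times the
    ## illumination field, over a dim background
    mk <- matrix(0, h, w)
    if (n) {
        for (i in seq_len(n)) {
            sig <- 0.5 * sqrt(cellDf$a[i] * cellDf$b[i])
            ext <- ceiling(3 * sig)
            r0 <- max(1L, round(cellDf$cy[i]) - ext)
            r1 <- min(h, round(cellDf$cy[i]) + ext)
            c0 <- max(1L, round(cellDf$cx[i]) - ext)
            c1 <- min(w, round(cellDf$cx[i]) + ext)
            rr <- r0:r1; cc <- c0:c1
            g <- exp(-outer((rr - cellDf$cy[i])^2,
                            (cc - cellDf$cx[i])^2, "+") / (2 * sig^2))
            mk[rr, cc] <- mk[rr, cc] + res$markerTotalTrue[i] * g / sum(g)
        }
    }
    mk <- (mk + cfg$markerBackground) * illum
    base$marker <- mk

    offs <- focalOffsetsFor(cfg$nFocalPlanes)
    nP <- cfg$nFocalPlanes * cfg$nTimePlanes
    channels <- lapply(base, function(bx) {
        out <- array(0L, c(h, w, nP))
        for (f in seq_along(offs)) {
            pf <- if (offs[f] == 0) bx else
                EBImage::gblur(bx, sigma = cfg$blurPerUm * abs(offs[f]))
            for (t in seq_len(cfg$nTimePlanes)) {
                noisy <- pf + if (cfg$noiseSd > 0)
                    matrix(rnorm(h * w, 0, cfg$noiseSd), h, w) else 0
                out[, , (f - 1L) * cfg$nTimePlanes + t] <- quantize16(noisy)
            }
        }
        out
    })
    new("FieldImage", channels = channels, dish = as.integer(dish),
        field = as.integer(field), focalOffsets = offs,
        timeIndices = seq_len(cfg$nTimePlanes), pixelSize = cfg$pixelSize)
}

#' Render single-cell patches directly
#'
#' Renders individual cells of the same generative model as
#' \code{\link{generateField}} (type-dependent ellipse geometry, band-passed
#' internal texture, phase halo, sensor noise, per-dish illumination gain)
#' straight into crop-sized patches, one centred cell per patch. This skips
#' field assembly and segmentation and is the cheap path for experiments
#' that need many cells with known labels — e.g. classifier learning-curve
#' sweeps — where the quantity under study is the classifier, not the
#' segmentation.
#'
#' @param config a \code{SyntheticConfig}; cell-level parameters
#'   (\code{sizeMeans}, \code{sizeSd}, \code{textureEffect},
#'   \code{typeFraction}, \code{noiseSd}, \code{dishIllumSd}) apply.
#' @param n number of cells to render.
#' @param dishes dish ids to cycle cells over (per-dish illumination gains
#'   are drawn once per dish).
#' @param channels channel roles to render (any of \code{"ph"},
#'   \code{"dic"}, \code{"bf"}).
#' @param cropSize patch edge length.
#' @param includeContour also emit the binary \code{"contour"} crop
#'   channel (off by default: patch sets exist for classifier sweeps, and
#'   every crop channel costs \code{8 * cropSize^2 * n} bytes).
#' @param seed RNG seed (independent of \code{config$seed}).
#' @return a \code{\link{CellSet}} whose manifest carries \code{label} and
#'   \code{true_type} (the known type) and \code{area_px} (rasterised cell
#'   area).
#' @export
generateCellPatches <- function(config, n, dishes = 1L,
                                channels = "dic", cropSize = 150L,
                                includeContour = FALSE, seed = 1L) {
    validateSyntheticConfig(config)
    stopifnot(isCount(n), all(channels %in% c("ph", "dic", "bf")))
    s <- as.integer(cropSize)
    ctr <- floor(s / 2) + 1
    gains <- withSeed(subSeed(seed, 880L),
                      stats::setNames(exp(rnorm(length(dishes), 0,
                                                config$dishIllumSd)),
                                      dishes))
    dish <- rep(as.integer(dishes), length.out = n)
    withSeed(subSeed(seed, 881L), {
        type <- ifelse(runif(n) < config$typeFraction, "proB", "LMPP")
        area <- pmax(rnorm(n, config$sizeMeans[ifelse(type == "proB",
                                                      2L, 1L)],
                           config$sizeSd), 400)
        q <- runif(n, 0.85, 1)
        a <- sqrt(area / pi) / sqrt(q)
        b <- sqrt(area / pi) * sqrt(q)
        theta <- runif(n, 0, pi)
        lvl <- list(ph = c(1, 0.55, 1.6), dic = c(1, 1.12, 1),
                    bf = c(1, 0.9, 1))
        crops <- stats::setNames(lapply(channels, function(ch)
            array(0, c(s, s, n))), channels)
        contour <- if (includeContour) array(0, c(s, s, n)) else NULL
        areaPx <- integer(n)
        dy <- matrix(seq_len(s) - ctr, s, s)
        dx <- t(dy)
        for (i in seq_len(n)) {
            u <- dx * cos(theta[i]) + dy * sin(theta[i])
            v <- -dx * sin(theta[i]) + dy * cos(theta[i])
            body <- (u / a[i])^2 + (v / b[i])^2 <= 1
            areaPx[i] <- sum(body)
            if (includeContour) contour[, , i] <- body * 1
            rim <- EBImage::dilate(body * 1,
                                   EBImage::makeBrush(5, "disc")) > 0 & !body
            sdTex <- config$textureBaseSd *
                (1 + config$textureEffect * (type[i] == "proB"))
            g <- gains[as.character(dish[i])]
            for (ch in channels) {
                base <- matrix(config$bgLevel * lvl[[ch]][1], s, s)
                base[body] <- config$bgLevel * lvl[[ch]][2]
                base[rim] <- config$bgLevel * lvl[[ch]][3]
                if (sdTex > 0) {
                    wn <- matrix(rnorm(s * s), s, s)
                    bp <- EBImage::gblur(wn, sigma = 1.5) -
                        EBImage::gblur(wn, sigma = 4)
                    base <- base + (bp / sd(bp)) * sdTex * body
                }
                crops[[ch]][, , i] <-
                    quantize16(base * g +
                               matrix(rnorm(s * s, 0, config$noiseSd), s, s))
            }
        }
        if (includeContour) crops[["contour"]] <- contour
        man <- DataFrame(cell_id = seq_len(n), dish = dish,
                         field = rep(0L, n),
                         cx = rep(ctr, n), cy = rep(ctr, n),
                         area_px = areaPx,
                         label = factor(type,
                                        levels = c("LMPP", "proB",
                                                   "unused")),
                         true_type = type)
        new("CellSet", crops = crops, manifest = man, cropSize = s)
    })
}

#' Generate a full synthetic experiment
#'
#' Generates \code{nDishes x fieldsPerDish} fields. Dish-level illumination
#' gains are drawn once per dish and shared by all its fields; everything is
#' reproducible from \code{config$seed}.
#'
#' @inheritParams generateField
#' @return a list of \code{list(field, truth)} entries (fields nested within
#'   dishes, dish-major order), with attribute \code{"dishEffects"}.
#' @export
generateExperiment <- function(config, render = TRUE) {
    validateSyntheticConfig(config)
    out <- vector("list", config$nDishes * config$fieldsPerDish)
    dishEffects <- lapply(seq_len(config$nDishes), function(d)
        withSeed(subSeed(config$seed, d, 0L, 990L),
                 list(illumGain = exp(rnorm(1, 0, config$dishIllumSd)))))
    idOffset <- 0L
    k <- 1L
    for (d in seq_len(config$nDishes)) {
        for (f in seq_len(config$fieldsPerDish)) {
            out[[k]] <- generateField(config, dish = d, field = f,
                                      dishEffects = dishEffects[[d]],
                                      idOffset = idOffset, render = render)
            idOffset <- idOffset + nrow(cells(out[[k]]$truth))
            k <- k + 1L
        }
    }
    attr(out, "dishEffects") <- dishEffects
    out
}
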