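#' Otsu threshold of an intensity image
#'
#' Classical histogram thresholding maximising the between-class variance.
#' The histogram uses 256 bins spanning the image min-max range; candidate
#' thresholds are the interior bin edges, and the between-class variance at
#' each candidate is computed from exact per-bin sums of the raw pixel
#' values (not bin centres), so the result equals exhaustive maximisation
#' over the same candidate set. Ties take the lowest threshold.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param levels number of histogram bins.
#' @return the threshold; pixels \code{<= threshold} form the lower class.
#' @export
otsuThreshold <- function(image, levels = 256L) {
    x <- as.vector(image)
    rng <- range(x)
    if (rng[1] == rng[2])
        stop("no threshold exists: image is constant")
    edges <- seq(rng[1], rng[2], length.out = levels + 1L)
    ## left-open bins (e_i, e_{i+1}] so that a split after bin k puts
    ## exactly the pixels <= edges[k+1] in the lower class
    bin <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
    bin[bin == 0L] <- 1L
    cnt <- tabulate(bin, nbins = levels)
    sums <- vapply(seq_len(levels), function(b) sum(x[bin == b]), 0)
    n <- length(x)
    cumN <- cumsum(cnt)[-levels]
    cumS <- cumsum(sums)[-levels]
    w0 <- cumN / n
    w1 <- 1 - w0
    mu0 <- ifelse(cumN > 0, cumS / cumN, 0)
    mu1 <- ifelse(n - cumN > 0, (sum(sums) - cumS) / (n - cumN), 0)
    bcv <- w0 * w1 * (mu0 - mu1)^2
    bcv[cumN == 0 | cumN == n] <- -Inf
    ## ties (e.g. adjacent cut points with no pixels between them) go to
    ## the lowest threshold; the relative tolerance absorbs float noise of
    ## the cumulative-sum route so mathematically equal candidates tie
    best <- max(bcv)
    edges[which(bcv >= best - 1e-9 * abs(best))[1] + 1L]
}

#' Binarise and clean a field image
#'
#' Thresholds the segmentation channel and applies the morphological
#' clean-up chain: closing, removal of components touching the image
#' border, and hole filling. Phase-contrast cell bodies are darker than
#' background, so the default polarity takes pixels below the threshold as
#' foreground.
#'
#' @param image numeric matrix.
#' @param threshold intensity threshold (see \code{\link{otsuThreshold}}).
#' @param polarity \code{"dark"} (foreground below threshold) or
#'   \code{"bright"}.
#' @param closingRadius radius (px) of the disc structuring element used
#'   for closing.
#' @return logical foreground mask.
#' @export
binarizeAndClean <- function(image, threshold, polarity = c("dark", "bright"),
                             closingRadius = 3L) {
    polarity <- match.arg(polarity)
    fg <- if (polarity == "dark") image <= threshold else image > threshold
    if (closingRadius > 0) {
        brush <- EBImage::makeBrush(2L * closingRadius + 1L, "disc")
        fg <- EBImage::closing(fg * 1, brush) > 0
    }
    fg <- clearBorder(fg)
    fg <- EBImage::fillHull(fg * 1) > 0
    if (!any(fg))
        warning("empty foreground after cleaning")
    fg
}

## Remove connected components touching the image border (8-connectivity).
clearBorder <- function(mask) {
    lab <- EBImage::bwlabel(mask * 1)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    if (length(border)) mask[lab %in% border] <- FALSE
    mask
}

## Local maxima of a surface within a mask with a minimum peak separation.
## Plateau duplicates and close pairs are resolved deterministically by
## column-major scan order (first peak wins).
localPeaks <- function(surface, mask, minDistance = 10) {
    mx <- EBImage::dilate(surface,
                          EBImage::makeBrush(2L * ceiling(minDistance) + 1L,
                                             "disc"))
    cand <- which(mask & surface == mx & surface > 0)
    if (!length(cand)) return(matrix(numeric(0), 0, 2))
    nr <- nrow(surface)
    ry <- (cand - 1L) %% nr + 1L
    rx <- (cand - 1L) %/% nr + 1L
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
        if (!any(keep)) { keep[i] <- TRUE; next }
        sel <- which(keep)
        if (all((ry[sel] - ry[i])^2 + (rx[sel] - rx[i])^2 >= minDistance^2))
            keep[i] <- TRUE
    }
    cbind(row = ry[keep], col = rx[keep])
}

#' Split touching cells by marker-seeded watershed
#'
#' Computes the Euclidean distance transform of the foreground mask,
#' smooths it with a Gaussian filter, takes its local maxima as markers and
#' grows the markers over the mask (watershed on the negated smoothed
#' distance surface). Components holding a single marker pass through
#' unsplit.
#'
#' @param mask logical foreground mask.
#' @param edtSigma Gaussian smoothing sigma (px) applied to the distance
#'   transform.
#' @param minPeakDistance minimum marker separation (px).
#' @return a \code{\link{RegionLabelMap}}.
#' @export
splitTouching <- function(mask, edtSigma = 4, minPeakDistance = 10) {
    if (!any(mask)) return(emptyRegionMap(dim(mask)))
    edt <- EBImage::distmap(mask * 1)
    sedt <- EBImage::gblur(edt, sigma = edtSigma)
    sedt[!mask] <- 0
    pk <- localPeaks(sedt, mask, minPeakDistance)
    if (nrow(pk) == 0L) return(emptyRegionMap(dim(mask)))
    seeds <- matrix(0L, nrow(mask), ncol(mask))
    seeds[cbind(pk[, 1], pk[, 2])] <- seq_len(nrow(pk))
    lab <- .seededWatershed(sedt, seeds, mask)
    ## cover mask pixels unreachable by propagation (isolated specks with no
    ## marker): assign each its own component label
    orphan <- mask & lab == 0L
    if (any(orphan)) {
        ol <- EBImage::bwlabel(orphan * 1)
        lab[orphan] <- max(lab) + ol[orphan]
    }
    buildRegionMap(lab)
}

emptyRegionMap <- function(d) {
    new("RegionLabelMap", labels = matrix(0L, d[1], d[2]),
        table = DataFrame(label = integer(0), area_px = integer(0),
                          cx = numeric(0), cy = numeric(0),
                          bbox_r0 = integer(0), bbox_r1 = integer(0),
                          bbox_c0 = integer(0), bbox_c1 = integer(0)))
}

## Relabel consecutively and build the region table from a label matrix.
buildRegionMap <- function(lab) {
    ids <- sort(unique(lab[lab > 0L]))
    if (!length(ids)) return(emptyRegionMap(dim(lab)))
    lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
    idx <- which(lab > 0L)
    g <- lab[idx]
    nr <- nrow(lab)
    ry <- (idx - 1L) %% nr + 1L
    rx <- (idx - 1L) %/% nr + 1L
    area <- tabulate(g, nbins = length(ids))
    tab <- DataFrame(label = seq_along(ids),
                     area_px = as.integer(area),
                     cx = as.numeric(tapply(rx, g, mean)),
                     cy = as.numeric(tapply(ry, g, mean)),
                     bbox_r0 = as.integer(tapply(ry, g, min)),
                     bbox_r1 = as.integer(tapply(ry, g, max)),
                     bbox_c0 = as.integer(tapply(rx, g, min)),
                     bbox_c1 = as.integer(tapply(rx, g, max)))
    new("RegionLabelMap", labels = lab, table = tab)
}

#' Filter segmented regions by pixel area
#'
#' Keeps regions with \code{minPx < area < maxPx} (both bounds exclusive:
#' regions at or below the lower bound and at or above the upper bound are
#' removed) and relabels survivors consecutively. At the emulated pixel
#' resolution of 162.5 nm/px the default band (2000, 8000) px corresponds
#' to physical areas of 52.81 to 211.2 square micrometres.
#'
#' @param regions a \code{\link{RegionLabelMap}}.
#' @param minPx,maxPx exclusive area bounds in pixels.
#' @return a filtered \code{\link{RegionLabelMap}}.
#' @export
filterByArea <- function(regions, minPx = 2000, maxPx = 8000) {
    tab <- regionTable(regions)
    keep <- tab$label[tab$area_px > minPx & tab$area_px < maxPx]
    lab <- labelMask(regions)
    lab[!(lab %in% keep)] <- 0L
    buildRegionMap(lab)
}

#' Pixel-to-physical area conversion
#'
#' @param areaPx area in pixels.
#' @param pixelSize pixel edge in nanometres.
#' @return area in square micrometres.
#' @export
areaToUm2 <- function(areaPx, pixelSize = 162.5) {
    areaPx * (pixelSize / 1000)^2
}

#' Segment one field
#'
#' Full segmentation chain on the reference (in-focus) plane of the
#' segmentation channel: Otsu threshold, binarise + clean, watershed split,
#' area filter.
#'
#' @param field a \code{\link{FieldImage}}.
#' @param channel channel role to segment (default \code{"ph"}).
#' @param polarity,closingRadius see \code{\link{binarizeAndClean}}.
#' @param edtSigma,minPeakDistance see \code{\link{splitTouching}}.
#' @param minPx,maxPx see \code{\link{filterByArea}}.
#' @return a \code{\link{RegionLabelMap}}.
#' @export
segmentField <- function(field, channel = "ph",
                         polarity = c("dark", "bright"), closingRadius = 3L,
                         edtSigma = 4, minPeakDistance = 10,
                         minPx = 2000, maxPx = 8000) {
    polarity <- match.arg(polarity)
    refPlane <- which(field@focalOffsets == 0)[1]
    if (is.na(refPlane)) refPlane <- 1L
    ## plane index accounts for time-major nesting within each focal plane
    img <- field@channels[[channel]][, ,
        (refPlane - 1L) * length(field@timeIndices) + 1L]
    thr <- otsuThreshold(img)
    fg <- binarizeAndClean(img, thr, polarity, closingRadius)
    regions <- splitTouching(fg, edtSigma, minPeakDistance)
    filterByArea(regions, minPx, maxPx)
}
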