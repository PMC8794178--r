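#' Flat-field correction of the fluorescence marker channel
#'
#' Divides the marker image by a heavily blurred copy of itself
#' (Gaussian sigma 200 px, mirror-reflected boundaries), removing smooth
#' illumination and background structure before per-cell totals are taken.
#' Computed on the full field, before cropping.
#'
#' @param markerImage numeric matrix.
#' @param sigma blur sigma in pixels.
#' @param floorFrac divisor floor as a fraction of the image mean; a blurred
#'   value at or below the floor anywhere is an error (pathological input).
#' @return the flattened image (dimensionless, ~1 in background).
#' @export
flattenMarkerChannel <- function(markerImage, sigma = 200, floorFrac = 1e-6) {
    floorVal <- floorFrac * mean(markerImage)
    blurred <- gblurReflect(markerImage, sigma)
    bad <- which(blurred <= floorVal)
    if (length(bad)) {
        nr <- nrow(markerImage)
        stop(sprintf(paste0("flat-field divisor at or below floor at pixel ",
                            "(row %d, col %d)"),
                     (bad[1] - 1L) %% nr + 1L, (bad[1] - 1L) %/% nr + 1L))
    }
    markerImage / blurred
}

#' Crop single cells from a field
#'
#' Produces one square crop per requested channel/plane per segmented
#' region, centred on the region centroid (rounded to the nearest pixel),
#' plus the binary contour crop of the region itself and the flattened
#' marker crop. Intensity channels are cropped raw, so neighbouring cells
#' remain visible; the later circular mask (not the segmentation mask)
#' limits what the classifier sees. Cells whose window would leave the
#' field are skipped and reported in the \code{"skipped"} attribute.
#'
#' @param field a \code{\link{FieldImage}}.
#' @param regions a \code{\link{RegionLabelMap}} for that field.
#' @param channels channel roles to crop (default all transmitted-light
#'   roles present).
#' @param cropSize crop edge length (px).
#' @param flattenSigma sigma for \code{\link{flattenMarkerChannel}}; set to
#'   \code{NULL} to crop the raw marker channel.
#' @param allPlanes if \code{TRUE}, crop every focal/time plane of each
#'   requested channel (keys like \code{"dic.z+1.2"}, \code{"bf.t2"});
#'   otherwise only the in-focus reference plane.
#' @return a \code{\link{CellSet}} whose manifest rows carry the full-field
#'   region area (\code{area_px}) and centroid.
#' @export
cropCells <- function(field, regions, channels = NULL, cropSize = 150L,
                      flattenSigma = 200, allPlanes = FALSE) {
    stopifnot(is(field, "FieldImage"), is(regions, "RegionLabelMap"))
    if (is.null(channels))
        channels <- intersect(c("ph", "dic", "bf"), channelNames(field))
    tab <- regionTable(regions)
    lab <- labelMask(regions)
    h <- nrow(lab); w <- ncol(lab)
    half <- cropSize %/% 2L                       # 75 for 150: rows r-75..r+74
    cy <- round(tab$cy); cx <- round(tab$cx)
    okRow <- cy - half >= 1L & cy + half - 1L <= h
    okCol <- cx - half >= 1L & cx + half - 1L <= w
    keep <- which(okRow & okCol)
    skipped <- tab$label[!(okRow & okCol)]

    nT <- length(field@timeIndices)
    planeKeys <- function(role) {
        if (!allPlanes) {
            refPlane <- which(field@focalOffsets == 0)[1]
            if (is.na(refPlane)) refPlane <- 1L
            idx <- (refPlane - 1L) * nT + 1L
            stats::setNames(idx, role)
        } else {
            keys <- character(0); idx <- integer(0)
            for (f in seq_along(field@focalOffsets)) {
                for (t in seq_len(nT)) {
                    key <- role
                    if (length(field@focalOffsets) > 1L)
                        key <- sprintf("%s.z%+.1f", key,
                                       field@focalOffsets[f])
                    if (nT > 1L) key <- sprintf("%s.t%d", key, t)
                    keys <- c(keys, key)
                    idx <- c(idx, (f - 1L) * nT + t)
                }
            }
            stats::setNames(idx, keys)
        }
    }

    n <- length(keep)
    crops <- list()
    window <- function(img, i) {
        r <- cy[keep[i]]; c <- cx[keep[i]]
        img[(r - half):(r + half - 1L), (c - half):(c + half - 1L)]
    }
    for (role in channels) {
        pk <- planeKeys(role)
        for (j in seq_along(pk)) {
            a <- array(0, c(cropSize, cropSize, n))
            img <- field@channels[[role]][, , pk[j]]
            for (i in seq_len(n)) a[, , i] <- window(img, i)
            crops[[names(pk)[j]]] <- a
        }
    }
    ## contour crop: the generating region only, other cells zeroed
    contour <- array(0, c(cropSize, cropSize, n))
    for (i in seq_len(n))
        contour[, , i] <- (window(lab, i) == tab$label[keep[i]]) * 1
    crops[["contour"]] <- contour
    ## flattened marker crop (labelling only, never classifier input)
    if ("marker" %in% channelNames(field)) {
        refPlane <- which(field@focalOffsets == 0)[1]
        if (is.na(refPlane)) refPlane <- 1L
        mimg <- field@channels[["marker"]][, , (refPlane - 1L) * nT + 1L]
        if (!is.null(flattenSigma))
            mimg <- flattenMarkerChannel(mimg, flattenSigma)
        a <- array(0, c(cropSize, cropSize, n))
        for (i in seq_len(n)) a[, , i] <- window(mimg, i)
        crops[["marker"]] <- a
    }
    man <- DataFrame(cell_id = tab$label[keep],
                     dish = rep(field@dish, n),
                     field = rep(field@field, n),
                     cx = as.numeric(cx[keep]), cy = as.numeric(cy[keep]),
                     area_px = as.integer(tab$area_px[keep]))
    out <- new("CellSet", crops = crops, manifest = man,
               cropSize = as.integer(cropSize))
    attr(out, "skipped") <- skipped
    out
}

#' Combine CellSets from several fields into one experiment-level set
#'
#' Cell ids are made globally unique by offsetting per input set.
#'
#' @param sets list of \code{\link{CellSet}} objects with identical crop
#'   channel keys.
#' @return a single \code{\link{CellSet}}.
#' @export
combineCellSets <- function(sets) {
    sets <- sets[vapply(sets, function(s) nrow(manifest(s)) > 0, TRUE)]
    if (!length(sets)) stop("no non-empty CellSet to combine")
    keys <- names(sets[[1]]@crops)
    for (s in sets)
        if (!identical(names(s@crops), keys))
            stop("crop channel keys differ between sets")
    crops <- stats::setNames(lapply(keys, function(k) {
        arrs <- lapply(sets, function(s) s@crops[[k]])
        out <- array(0, c(dim(arrs[[1]])[1:2],
                          sum(vapply(arrs, function(a) dim(a)[3], 0L))))
        at <- 0L
        for (a in arrs) {
            out[, , at + seq_len(dim(a)[3])] <- a
            at <- at + dim(a)[3]
        }
        out
    }), keys)
    mans <- lapply(sets, manifest)
    off <- 0L
    for (i in seq_along(mans)) {
        mans[[i]]$cell_id <- mans[[i]]$cell_id + off
        off <- off + max(mans[[i]]$cell_id)
    }
    new("CellSet", crops = crops, manifest = do.call(rbind, mans),
        cropSize = sets[[1]]@cropSize)
}
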