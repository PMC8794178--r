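#' Write a field as multi-page 16-bit TIFFs
#'
#' One TIFF per channel (pages = planes, focal-major then time order) plus
#' a JSON sidecar documenting dish, field, plane order, focal offsets and
#' pixel size.
#'
#' @param field a \code{\link{FieldImage}}.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
writeFieldTIFF <- function(field, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stem <- sprintf("d%02d_f%03d", field@dish, field@field)
    paths <- character(0)
    for (ch in channelNames(field)) {
        a <- field@channels[[ch]]
        pages <- lapply(seq_len(dim(a)[3]), function(p) a[, , p] / 65535)
        path <- file.path(dir, sprintf("%s_%s.tif", stem, ch))
        tiff::writeTIFF(pages, path, bits.per.sample = 16L)
        paths <- c(paths, path)
    }
    sidecar <- file.path(dir, sprintf("%s_planes.json", stem))
    jsonlite::write_json(
        list(dish = field@dish, field = field@field,
             channels = channelNames(field),
             planeOrder = "focal-major, time-minor",
             focalOffsets = field@focalOffsets,
             timeIndices = field@timeIndices,
             pixelSizeNm = field@pixelSize),
        sidecar, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, sidecar))
}

#' Read a field back from TIFFs written by \code{\link{writeFieldTIFF}}
#'
#' @param dir directory holding the TIFFs and sidecar.
#' @param dish,field identifiers of the field to read.
#' @return a \code{\link{FieldImage}} with integer pixel values restored
#'   exactly.
#' @export
readFieldTIFF <- function(dir, dish, field) {
    stem <- sprintf("d%02d_f%03d", dish, field)
    meta <- jsonlite::read_json(file.path(dir,
                                          sprintf("%s_planes.json", stem)),
                                simplifyVector = TRUE)
    channels <- list()
    for (ch in meta$channels) {
        pages <- tiff::readTIFF(file.path(dir,
                                          sprintf("%s_%s.tif", stem, ch)),
                                all = TRUE)
        a <- array(0L, c(dim(pages[[1]]), length(pages)))
        for (p in seq_along(pages))
            a[, , p] <- quantize16(pages[[p]] * 65535)
        channels[[ch]] <- a
    }
    new("FieldImage", channels = channels, dish = as.integer(dish),
        field = as.integer(field),
        focalOffsets = as.numeric(meta$focalOffsets),
        timeIndices = as.integer(meta$timeIndices),
        pixelSize = as.numeric(meta$pixelSizeNm))
}

#' Write ground truth (cell table + label mask)
#'
#' The cell table goes to CSV; the label mask to a 16-bit label TIFF.
#'
#' @param truth a \code{\link{GroundTruth}}.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeGroundTruth <- function(truth, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tc <- cells(truth)
    if (nrow(tc)) {
        stem <- sprintf("d%02d_f%03d", tc$dish[1], tc$field[1])
    } else stem <- "empty"
    csv <- file.path(dir, sprintf("%s_truth.csv", stem))
    utils::write.csv(as.data.frame(tc), csv, row.names = FALSE)
    ## label ids are per-experiment; store mod 65535 (documented) if large
    msk <- file.path(dir, sprintf("%s_truthmask.tif", stem))
    tiff::writeTIFF(labelMask(truth) %% 65536 / 65535, msk,
                    bits.per.sample = 16L)
    invisible(c(csv, msk))
}

#' Write a segmentation result
#'
#' @param regions a \code{\link{RegionLabelMap}}.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return invisibly, the written paths.
#' @export
writeRegionMap <- function(regions, dir, stem = "regions") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(dir, sprintf("%s.csv", stem))
    utils::write.csv(as.data.frame(regionTable(regions)), csv,
                     row.names = FALSE)
    msk <- file.path(dir, sprintf("%s_mask.tif", stem))
    tiff::writeTIFF(labelMask(regions) %% 65536 / 65535, msk,
                    bits.per.sample = 16L)
    invisible(c(csv, msk))
}

#' Write a CellSet manifest to CSV
#'
#' @param cellSet a \code{\link{CellSet}}.
#' @param path output CSV path.
#' @export
writeManifestCSV <- function(cellSet, path) {
    utils::write.csv(as.data.frame(manifest(cellSet)), path,
                     row.names = FALSE)
    invisible(path)
}

#' Write a CellSet crop archive
#'
#' Per-channel crops are stored as raw little-endian doubles in
#' column-major cell-major order (one \code{.bin} per channel key), with a
#' JSON header documenting dimensions and key order, plus the manifest
#' CSV. \code{\link{readCellSet}} restores the set bit-exactly.
#'
#' @param cellSet a \code{\link{CellSet}}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeCellSet <- function(cellSet, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    keys <- names(cellSet@crops)
    for (k in keys) {
        con <- file(file.path(dir, paste0(gsub("[^A-Za-z0-9_.+-]", "_", k),
                                          ".bin")), "wb")
        writeBin(as.vector(cellSet@crops[[k]]), con, size = 8,
                 endian = "little")
        close(con)
    }
    jsonlite::write_json(list(keys = keys, cropSize = cellSet@cropSize,
                              n = length(cellSet),
                              layout = "column-major, cells last"),
                         file.path(dir, "header.json"), auto_unbox = TRUE,
                         digits = NA)
    writeManifestCSV(cellSet, file.path(dir, "manifest.csv"))
    invisible(dir)
}

#' Read a CellSet crop archive
#'
#' @param dir directory written by \code{\link{writeCellSet}}.
#' @return a \code{\link{CellSet}}.
#' @export
readCellSet <- function(dir) {
    hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                               simplifyVector = TRUE)
    s <- as.integer(hdr$cropSize); n <- as.integer(hdr$n)
    crops <- list()
    for (k in hdr$keys) {
        con <- file(file.path(dir, paste0(gsub("[^A-Za-z0-9_.+-]", "_", k),
                                          ".bin")), "rb")
        v <- readBin(con, "double", n = s * s * n, size = 8,
                     endian = "little")
        close(con)
        crops[[k]] <- array(v, c(s, s, n))
    }
    man <- utils::read.csv(file.path(dir, "manifest.csv"))
    if ("label" %in% colnames(man))
        man$label <- factor(man$label, levels = c("LMPP", "proB", "unused"))
    new("CellSet", crops = crops, manifest = DataFrame(man), cropSize = s)
}
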