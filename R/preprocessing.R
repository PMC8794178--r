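#' Circular mask around the crop centre
#'
#' Zeroes pixels at Euclidean distance >= \code{radius} from the crop
#' centre; inside pixels are untouched. Applied to every classifier input
#' channel so the classifier cannot exploit segmentation-mask shape.
#'
#' @param crop square numeric matrix.
#' @param radius mask radius (px).
#' @return masked crop.
#' @export
applyCircularMask <- function(crop, radius = 50) {
    if (nrow(crop) != ncol(crop))
        stop("crop must be square")
    crop * discMask(nrow(crop), radius)
}

#' Normalise a masked crop to inside-mask mean 1
#'
#' Scales the crop so the mean over pixels inside the circular mask is
#' exactly 1; outside pixels stay 0. Scale-invariant: a rescaled input
#' yields the identical output.
#'
#' @param maskedCrop square numeric matrix already circularly masked.
#' @param radius mask radius (px) used.
#' @return normalised crop, or \code{NULL} if the inside-mask mean is not
#'   positive (cell excluded upstream).
#' @export
normalizeMean <- function(maskedCrop, radius = 50) {
    m <- mean(maskedCrop[discMask(nrow(maskedCrop), radius)])
    if (!is.finite(m) || m <= 0) return(NULL)
    maskedCrop / m
}

#' Balance cell counts across dishes and types by random trimming
#'
#' Subsamples every (dish, label) cell list without replacement down to the
#' common count \code{C* = min over (dish, type) of C_{dish,type}},
#' reproducibly from \code{seed}. Applied once per experiment, before any
#' channel-specific training, so all channel configurations see the same
#' cells.
#'
#' @param cellSet a labelled \code{\link{CellSet}} (manifest has
#'   \code{label}).
#' @param seed trim seed (kept distinct from classifier init seeds so
#'   init-variation experiments hold the data fixed).
#' @return the trimmed \code{\link{CellSet}}; attribute \code{"Cstar"}
#'   records the common count.
#' @export
trimToBalance <- function(cellSet, seed = 1L) {
    man <- manifest(cellSet)
    if (!"label" %in% colnames(man))
        stop("cellSet must be labelled before trimming")
    use <- which(man$label %in% c("LMPP", "proB"))
    if (!length(use)) stop("no labelled cells to balance")
    key <- interaction(man$dish[use], droplevels(factor(man$label[use])),
                       drop = FALSE)
    cnt <- table(key)
    if (any(cnt == 0))
        stop("empty (dish, type) group: ",
             paste(names(cnt)[cnt == 0], collapse = ", "))
    cstar <- min(cnt)
    sel <- withSeed(seed, {
        unlist(lapply(split(use, key), function(idx)
            sort(sample(idx, cstar))), use.names = FALSE)
    })
    out <- cellSet[sort(sel)]
    attr(out, "Cstar") <- as.integer(cstar)
    out
}

#' Assemble classifier input arrays
#'
#' Applies the circular mask and mean-1 normalisation per channel per cell
#' and stacks the requested crop channels into the CNN input layout
#' \code{size x size x channels x cells}. The marker channel is refused:
#' it defines the labels and must never be classifier input. Cells whose
#' inside-mask mean is non-positive in any requested channel are dropped
#' (attribute \code{"dropped"}).
#'
#' @param cellSet a \code{\link{CellSet}}.
#' @param channels character vector of crop channel keys, in stacking
#'   order.
#' @param radius mask radius (px).
#' @return list: \code{x} (input array), \code{manifest} (rows retained).
#' @export
prepareInputs <- function(cellSet, channels, radius = 50) {
    if (any(grepl("^marker", channels)))
        stop("the marker channel defines labels and cannot be a classifier ",
             "input")
    missing <- setdiff(channels, names(cellSet@crops))
    if (length(missing))
        stop("no such crop channel(s): ", paste(missing, collapse = ", "))
    s <- cellSet@cropSize
    n <- length(cellSet)
    dm <- discMask(s, radius)
    x <- array(0, c(s, s, length(channels), n))
    bad <- logical(n)
    for (ci in seq_along(channels)) {
        a <- crops(cellSet, channels[ci])
        for (i in seq_len(n)) {
            cr <- a[, , i] * dm
            m <- mean(cr[dm])
            if (!is.finite(m) || m <= 0) { bad[i] <- TRUE; next }
            x[, , ci, i] <- cr / m
        }
    }
    keep <- which(!bad)
    out <- list(x = x[, , , keep, drop = FALSE],
                manifest = manifest(cellSet)[keep, , drop = FALSE])
    attr(out, "dropped") <- which(bad)
    out
}
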