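## Internal helpers shared across modules.

## Evaluate `expr` under a fixed, fully specified RNG state and restore the
## caller's state afterwards. All stochastic steps in the package go through
## this so results are reproducible across sessions and platforms.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    expr
}

## Deterministic integer sub-seed derived from a base seed and stream
## indices; kept below 2^31.
subSeed <- function(seed, ...) {
    idx <- c(...)
    s <- as.double(seed) %% 2147483647
    for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
    as.integer(s)
}

## Logical disc: TRUE where the Euclidean distance from the centre pixel is
## strictly below `radius`. `size` is the square edge length; the centre is
## pixel (floor(size/2) + 1, floor(size/2) + 1) in 1-based coordinates,
## matching the crop-window convention in crop_cell.
discMask <- function(size, radius) {
    ctr <- floor(size / 2) + 1
    d2 <- (matrix(seq_len(size), size, size) - ctr)^2
    (d2 + t(d2)) < radius^2
}

## Gaussian blur with mirror-reflected boundaries. EBImage::gblur pads
## circularly through its FFT filter; reflection avoids wrap-around
## artefacts, which matters for the sigma = 200 px flat-field divisor.
gblurReflect <- function(x, sigma) {
    r <- min(2 * ceiling(3 * sigma) + 1, 2 * min(dim(x)) - 1)
    pad <- ceiling(r / 2)
    padr <- min(pad, nrow(x) - 1L)
    padc <- min(pad, ncol(x) - 1L)
    xp <- x[c(rev(seq_len(padr) + 1L), seq_len(nrow(x)),
              nrow(x) - seq_len(padr)), ]
    xp <- xp[, c(rev(seq_len(padc) + 1L), seq_len(ncol(x)),
                 ncol(x) - seq_len(padc))]
    b <- EBImage::gblur(xp, sigma = sigma, radius = r)
    b[padr + seq_len(nrow(x)), padc + seq_len(ncol(x))]
}

## Row/col index matrices for a given dim, cheaper than expand.grid.
rowIndexMatrix <- function(nr, nc) matrix(seq_len(nr), nr, nc)
colIndexMatrix <- function(nr, nc) matrix(seq_len(nc), nr, nc, byrow = TRUE)

## Clamp, scale and round to the 16-bit unsigned integer grid used for
## stored pixel data.
quantize16 <- function(x) {
    x <- round(x)
    x[x < 0] <- 0
    x[x > 65535] <- 65535
    storage.mode(x) <- "integer"
    x
}

isCount <- function(x) length(x) == 1L && is.finite(x) && x >= 0 &&
    x == as.integer(x)
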