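#' Pipeline configuration
#'
#' Assembles the full parameter set of a pipeline run: synthesis, then the
#' stage parameters of segmentation, cropping, labelling, preprocessing and
#' classification. Defaults are the pipeline's canonical values
#' (segmentation area band 2000/8000 px, crop 150 px, flat-field sigma
#' 200 px, labelling radius 30 px, posterior threshold 0.8, mask radius
#' 50 px, and the fixed CNN training protocol).
#'
#' @param synthesis a \code{\link{syntheticConfig}}.
#' @param segmentation,cropping,labelling,preprocessing,classifier stage
#'   parameter lists; supplied entries override defaults.
#' @param seed master seed for trim and classifier streams.
#' @return nested list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(synthesis = syntheticConfig(),
                           segmentation = list(), cropping = list(),
                           labelling = list(), preprocessing = list(),
                           classifier = list(), seed = 1L) {
    defaults <- list(
        synthesis = synthesis,
        segmentation = list(channel = "ph", polarity = "dark",
                            closingRadius = 3L, edtSigma = 4,
                            minPeakDistance = 10, minPx = 2000, maxPx = 8000),
        cropping = list(cropSize = 150L, flattenSigma = 200,
                        allPlanes = FALSE),
        labelling = list(radius = 30, threshold = 0.8),
        preprocessing = list(maskRadius = 50),
        classifier = list(kind = "cnn", channels = "dic",
                          maxEpochs = 30L, patience = 5L, batchSize = 32L,
                          alpha = 1e-4, valFraction = 0.1),
        seed = as.integer(seed))
    for (sec in c("segmentation", "cropping", "labelling", "preprocessing",
                  "classifier")) {
        ov <- get(sec)
        bad <- setdiff(names(ov), names(defaults[[sec]]))
        if (length(bad))
            stop(sprintf("unknown %s option(s): %s", sec,
                         paste(bad, collapse = ", ")))
        defaults[[sec]][names(ov)] <- ov
    }
    class(defaults) <- "PipelineConfig"
    defaults
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the \code{\link{pipelineConfig}} sections; the
#' \code{synthesis} section takes \code{\link{syntheticConfig}} argument
#' names. Unknown keys are an error listing the offending names.
#'
#' @param path YAML file path.
#' @return a \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- c("synthesis", "segmentation", "cropping", "labelling",
               "preprocessing", "classifier", "seed")
    bad <- setdiff(names(y), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    synth <- do.call(syntheticConfig, y$synthesis %||% list())
    pipelineConfig(synthesis = synth,
                   segmentation = y$segmentation %||% list(),
                   cropping = y$cropping %||% list(),
                   labelling = y$labelling %||% list(),
                   preprocessing = y$preprocessing %||% list(),
                   classifier = y$classifier %||% list(),
                   seed = y$seed %||% 1L)
}

## Polynomial rolling hash (31-bit) over the serialised configuration,
## for manifest identity.
configHash <- function(x) {
    raw <- serialize(x, NULL, version = 2)
    h <- 17
    for (b in as.integer(raw)) h <- (h * 131 + b + 1) %% 2147483647
    sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes simulate, segment, crop, label, trim and cross-validated
#' train/test in order, and returns a run manifest with per-stage counts
#' (cells cropped, labelled, used for training; attrition is monotone).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory; when given, per-field TIFFs, the
#'   ground-truth and cell manifests and the results tables are written
#'   beneath it.
#' @param evaluate run the classification stage (set \code{FALSE} to stop
#'   after trimming).
#' @param verbose print stage progress.
#' @return list: \code{manifest} (run metadata and counts),
#'   \code{cellSet} (trimmed, labelled), \code{labelModel},
#'   \code{evaluation} (an \code{\link{EvaluationResult}} or NULL).
#' @export
runPipeline <- function(config, outDir = NULL, evaluate = TRUE,
                        verbose = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    say <- function(...) if (verbose) message(sprintf(...))
    scfg <- config$synthesis
    say("simulate: %d dishes x %d fields", scfg$nDishes, scfg$fieldsPerDish)
    fields <- generateExperiment(scfg)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        for (fw in fields) {
            writeFieldTIFF(fw$field, outDir)
            writeGroundTruth(fw$truth, outDir)
        }
    }
    sg <- config$segmentation
    cr <- config$cropping
    sets <- vector("list", length(fields))
    for (k in seq_along(fields)) {
        f <- fields[[k]]$field
        say("segment + crop: dish %d field %d", f@dish, f@field)
        regions <- segmentField(f, channel = sg$channel,
                                polarity = sg$polarity,
                                closingRadius = sg$closingRadius,
                                edtSigma = sg$edtSigma,
                                minPeakDistance = sg$minPeakDistance,
                                minPx = sg$minPx, maxPx = sg$maxPx)
        cs <- cropCells(f, regions, cropSize = cr$cropSize,
                        flattenSigma = cr$flattenSigma,
                        allPlanes = cr$allPlanes)
        ## carry ground truth for synthetic evaluation: majority true type
        ## of each region's pixels
        cs <- attachTrueType(cs, regions, fields[[k]]$truth)
        sets[[k]] <- cs
    }
    cellSet <- combineCellSets(sets)
    nCropped <- length(cellSet)
    say("label: %d cells cropped", nCropped)
    lab <- labelCells(cellSet, radius = config$labelling$radius,
                      threshold = config$labelling$threshold,
                      seed = subSeed(config$seed, 11L))
    cellSet <- lab$cellSet
    labelled <- which(manifest(cellSet)$label %in% c("LMPP", "proB"))
    nLabelled <- length(labelled)
    say("trim: %d cells labelled", nLabelled)
    trimmed <- trimToBalance(cellSet[labelled],
                             seed = subSeed(config$seed, 12L))
    nUsed <- length(trimmed)
    ev <- NULL
    if (evaluate) {
        cl <- config$classifier
        say("train/test: %s on %s", cl$kind,
            paste(cl$channels, collapse = "+"))
        ev <- crossValidate(trimmed, classifier = cl$kind,
                            channels = cl$channels,
                            train = trainSpec(alpha = cl$alpha,
                                              batchSize = cl$batchSize,
                                              valFraction = cl$valFraction,
                                              patience = cl$patience,
                                              maxEpochs = cl$maxEpochs,
                                              seed = subSeed(config$seed,
                                                             13L)),
                            maskRadius = config$preprocessing$maskRadius)
    }
    man <- list(configHash = configHash(unclass(config)),
                seed = config$seed,
                nFields = length(fields),
                counts = c(cropped = nCropped, labelled = nLabelled,
                           used = nUsed),
                labelModel = list(means = lab$model@means,
                                  sds = lab$model@sds,
                                  weights = lab$model@weights,
                                  unusedInterval = lab$model@unusedInterval))
    if (!is.null(outDir)) {
        writeManifestCSV(trimmed, file.path(outDir, "cells.csv"))
        jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        if (!is.null(ev))
            utils::write.csv(as.data.frame(aucTable(ev)),
                             file.path(outDir, "auc.csv"),
                             row.names = FALSE)
    }
    list(manifest = man, cellSet = trimmed, labelModel = lab$model,
         evaluation = ev)
}

## Majority-vote true type per cropped region, from the synthetic mask.
attachTrueType <- function(cellSet, regions, truth) {
    man <- manifest(cellSet)
    lab <- labelMask(regions)
    gt <- labelMask(truth)
    tcells <- cells(truth)
    trueType <- rep(NA_character_, nrow(man))
    for (i in seq_len(nrow(man))) {
        px <- gt[lab == man$cell_id[i]]
        px <- px[px > 0L]
        if (!length(px)) next
        win <- names(which.max(table(px)))
        trueType[i] <- tcells$type[match(as.integer(win), tcells$cell_id)]
    }
    man$true_type <- trueType
    manifest(cellSet) <- man
    cellSet
}
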