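#' @include config.R flow-metrics.R classification.R psd.R synthetic.R
NULL

.measurementRecord <- function(id, sample, fm) {
    data.frame(image = id, sample = sample,
        fi = fm@fiPercent, ag = fm@agRatio,
        polarity = fm@polarity,
        powder_threshold = fm@powderThreshold,
        agglomerate_threshold = fm@agglomerateThreshold,
        bimodal = fm@bimodal,
        powder_pixels = fm@powderPixels, roi_pixels = fm@roiPixels,
        stringsAsFactors = FALSE)
}

# Default replicate grouping: filename prefix before the last "_" chunk,
# so scene_A_1.tif / scene_A_2.tif form one sample.
.sampleFromFilename <- function(path) {
    stem <- tools::file_path_sans_ext(basename(path))
    sub("_[^_]*$", "", stem)
}

#' Analyse a batch of flow-pattern images
#'
#' Runs [analyzeImage()] on every image, groups replicates by sample label,
#' and produces a ranked classification report. Unreadable or corrupt
#' images are reported per file and do not abort the batch. When `outDir`
#' is given, per-image records (`records.csv`, `records.json`) and the
#' ranked report (`report.csv`) are written; repeated runs on the same
#' inputs produce byte-identical files.
#'
#' @param paths image file paths, or a single directory (all PNG/TIFF
#'   inside are analysed in sorted order).
#' @param sampleLabels optional character vector of sample labels, one per
#'   image; default derives the label from the filename prefix before the
#'   trailing `_<replicate>` chunk.
#' @param config a [flowConfig()] list.
#' @param outDir optional output directory.
#' @return list with `records` (per-image data.frame), `report` (ranked
#'   sample summary), `failures` (data.frame of failed images and reasons)
#'   and `status` (0 on full success, 1 if any image failed).
#' @export
runAnalyze <- function(paths, sampleLabels = NULL, config = flowConfig(),
        outDir = NULL) {
    if (length(paths) == 1L && dir.exists(paths))
        paths <- sort(list.files(paths, "\\.(png|tif|tiff)$",
            full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0L) stop("no input images supplied")
    if (is.null(sampleLabels))
        sampleLabels <- vapply(paths, .sampleFromFilename, character(1),
            USE.NAMES = FALSE)
    stopifnot(length(sampleLabels) == length(paths))
    roiSpec <- if (is.character(config$roi)) parseRoiSpec(config$roi)
        else config$roi

    records <- list(); failures <- list()
    for (i in seq_along(paths)) {
        res <- tryCatch({
            img <- readFlowImage(paths[i])
            fm <- analyzeImage(img, roiSpec = roiSpec,
                polarity = config$polarity,
                minComponent = config$minComponent,
                bimodalityCut = config$bimodalityCut)
            .measurementRecord(basename(paths[i]), sampleLabels[i], fm)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            .logMsg(config, "info", "failed: ", paths[i], " (",
                conditionMessage(res), ")")
            failures[[length(failures) + 1L]] <- data.frame(
                image = paths[i], reason = conditionMessage(res),
                stringsAsFactors = FALSE)
        } else {
            records[[length(records) + 1L]] <- res
        }
    }
    records <- if (length(records)) do.call(rbind, records) else
        data.frame()
    rownames(records) <- NULL
    failures <- if (length(failures)) do.call(rbind, failures) else
        data.frame(image = character(0), reason = character(0))
    report <- if (nrow(records))
        rankReport(records, flowBands(lower = config$bandLower)) else
        data.frame()
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(records, file.path(outDir, "records.csv"),
            row.names = FALSE)
        jsonlite::write_json(records, file.path(outDir, "records.json"),
            dataframe = "rows", digits = NA, pretty = TRUE)
        utils::write.csv(report, file.path(outDir, "report.csv"),
            row.names = FALSE)
        if (nrow(failures))
            utils::write.csv(failures, file.path(outDir, "failures.csv"),
                row.names = FALSE)
    }
    list(records = records, report = report, failures = failures,
        status = if (nrow(failures)) 1L else 0L)
}

#' Generate synthetic fixtures from the command-line surface
#'
#' Thin wrapper over [makeFixtureSuite()]: either a single scene from
#' explicit parameters or a grid file (CSV with columns coverage,
#' ag_fraction, noise_sd, and optionally seed).
#'
#' @param outDir output directory.
#' @param gridFile optional CSV grid; when NULL one scene is generated.
#' @param coverage,agFraction,noiseSd single-scene parameters.
#' @param seed base seed (per-row seeds in the grid file override it).
#' @param ... passed to [sceneParams()].
#' @return invisibly, the manifest data.frame.
#' @export
runSimulate <- function(outDir, gridFile = NULL, coverage = 0.3,
        agFraction = 0, noiseSd = 5, seed = 1L, ...) {
    if (is.null(gridFile))
        return(makeFixtureSuite(outDir, coverage, agFraction, noiseSd,
            seeds = seed, ...))
    grid <- utils::read.csv(gridFile, stringsAsFactors = FALSE)
    need <- c("coverage", "ag_fraction")
    if (!all(need %in% names(grid)))
        stop("grid file must have columns coverage and ag_fraction")
    if (nrow(grid) == 0L) stop("empty fixture grid")
    if (!"noise_sd" %in% names(grid)) grid$noise_sd <- noiseSd
    if (!"seed" %in% names(grid)) grid$seed <- seed + seq_len(nrow(grid)) - 1L
    rows <- lapply(seq_len(nrow(grid)), function(i)
        makeFixtureSuite(outDir, grid$coverage[i], grid$ag_fraction[i],
            grid$noise_sd[i], seeds = grid$seed[i], ...))
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
        row.names = FALSE)
    invisible(manifest)
}

#' Summarise PSD replicate files
#'
#' Reads one or more PSD CSV files (each one or more replicates, see
#' [readPsdCsv()]) and reports Dv10/Dv50/Dv90 and span with replicate
#' statistics.
#'
#' @param paths CSV paths.
#' @param interp percentile interpolation mode.
#' @param outDir optional directory for `psd_summary.csv`.
#' @return the summary data.frame from [summarizePsd()].
#' @export
runPsd <- function(paths, interp = "log", outDir = NULL) {
    if (length(paths) == 0L) stop("no PSD files supplied")
    dists <- unlist(lapply(paths, readPsdCsv), recursive = FALSE)
    out <- summarizePsd(dists, interp)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(out, file.path(outDir, "psd_summary.csv"),
            row.names = FALSE)
    }
    out
}
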