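#' @include classification.R
NULL

#' Analysis run configuration
#'
#' Bundles every tunable analysis parameter with its documented default:
#' lighting polarity ("auto"), ROI (full frame), classification band lower
#' edges (0/10/30/50), bimodality gate (4.0), minimum powder component
#' (4 px), PSD interpolation ("log") and log level. Configurations
#' round-trip through YAML unchanged.
#'
#' @param polarity "auto", "backlight" or "frontlight".
#' @param roi ROI spec string ("x0,y0,w,h" or a mask image path) or NULL.
#' @param bandLower numeric lower edges of the flow classification bands.
#' @param bimodalityCut separability gate for AG.
#' @param minComponent smallest powder component kept (px).
#' @param psdInterp "log" or "linear" percentile interpolation.
#' @param logLevel "quiet", "info" or "debug".
#' @return list of class `flowConfig`.
#' @examples
#' cfg <- flowConfig(polarity = "backlight")
#' cfg$bandLower
#' @export
flowConfig <- function(polarity = "auto", roi = NULL,
        bandLower = c(0, 10, 30, 50), bimodalityCut = 4,
        minComponent = 4L, psdInterp = "log", logLevel = "info") {
    stopifnot(polarity %in% c("auto", "backlight", "frontlight"),
        psdInterp %in% c("log", "linear"),
        logLevel %in% c("quiet", "info", "debug"))
    structure(list(polarity = polarity, roi = roi,
        bandLower = as.numeric(bandLower),
        bimodalityCut = as.numeric(bimodalityCut),
        minComponent = as.integer(minComponent),
        psdInterp = psdInterp, logLevel = logLevel),
        class = "flowConfig")
}

#' Read a configuration file
#' @param path YAML file with any subset of the [flowConfig()] fields;
#'   missing fields take their defaults.
#' @return a `flowConfig` list.
#' @export
readFlowConfig <- function(path) {
    if (!file.exists(path)) stop("cannot read config file: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    known <- names(formals(flowConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config fields: ", paste(bad, collapse = ", "))
    do.call(flowConfig, vals)
}

#' Write a configuration file
#' @param config a `flowConfig` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeFlowConfig <- function(config, path) {
    stopifnot(inherits(config, "flowConfig"))
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

.logMsg <- function(config, level, ...) {
    levels <- c(quiet = 0, info = 1, debug = 2)
    if (levels[[config$logLevel]] >= levels[[level]])
        message(...)
}
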