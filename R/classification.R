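#' @include AllClasses.R
NULL

#' Default flow classification bands
#'
#' The four Flow Index bands used to rank flowability against
#' microcrystalline cellulose (MCC) boundary materials: MCC PH-200 marks
#' the Good/Excellent region and MCC PH-101 the Poor end, with MCC PH-102
#' at the boundary between acceptable and poor flow for high-speed
#' machinery. Bands are left-closed half-open intervals so each boundary
#' value belongs to the better class, and together they partition
#' [0, 100] exactly.
#'
#' @param lower numeric lower edges of the four bands, increasing, starting
#'   at 0.
#' @param labels band labels from worst to best.
#' @param boundaryMaterials reference material annotation per band.
#' @return data.frame with columns label, lower, upper, boundary_material.
#' @examples
#' flowBands()
#' @export
flowBands <- function(lower = c(0, 10, 30, 50),
        labels = c("Poor", "Acceptable", "Good", "Excellent"),
        boundaryMaterials = c("<< MCC PH-101",
            "MCC PH-102 to MCC PH-101",
            "MCC PH-200 to MCC PH-102",
            ">> MCC PH-200")) {
    if (length(lower) != length(labels))
        stop("one lower edge per band is required")
    if (lower[1] != 0 || is.unsorted(lower, strictly = TRUE) ||
        any(lower >= 100))
        stop("band edges must start at 0 and increase within [0, 100)")
    data.frame(label = labels, lower = lower,
        upper = c(lower[-1], 100),
        boundary_material = boundaryMaterials,
        stringsAsFactors = FALSE)
}

#' Classify a Flow Index into a flow band
#'
#' Maps FI values to the four-band classification: Poor on [0, 10),
#' Acceptable on [10, 30), Good on [30, 50), Excellent on [50, 100].
#' Vectorised.
#'
#' @param fi Flow Index value(s) in [0, 100].
#' @param bands a band table from [flowBands()].
#' @return ordered factor (worst to best) of band labels.
#' @examples
#' classifyFlow(c(28.35, 15.52, 55, 35, 5))
#' @export
classifyFlow <- function(fi, bands = flowBands()) {
    if (any(is.na(fi)) || any(fi < 0) || any(fi > 100))
        stop("FI must lie in [0, 100]")
    idx <- findInterval(fi, bands$lower)   # fi = 100 falls in the top band
    factor(bands$label[idx], levels = bands$label, ordered = TRUE)
}

#' Replicate mean and sample standard deviation
#'
#' Aggregates replicate measurements as mean plus sample (n - 1
#' denominator) standard deviation; the sd is reported as NA for a single
#' replicate.
#'
#' @param values numeric vector of replicate measurements.
#' @return list with `mean`, `sd` (NA when n = 1) and `n`.
#' @examples
#' summarizeReplicates(c(1, 2, 3))  # mean 2, sd 1
#' @export
summarizeReplicates <- function(values) {
    values <- as.numeric(values)
    if (length(values) == 0L || anyNA(values))
        stop("at least one non-missing replicate value is required")
    list(mean = mean(values),
        sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
        n = length(values))
}

#' Ranked flowability report over samples
#'
#' Aggregates per-sample FI and AG replicates (mean, sample sd, n),
#' classifies each sample by its mean FI, and sorts samples by decreasing
#' mean FI. Ties keep the input order.
#'
#' @param measurements data.frame with columns `sample`, `fi` and
#'   optionally `ag` (one row per replicate image).
#' @param bands classification bands, see [flowBands()].
#' @return data.frame: sample, n, fi_mean, fi_sd, ag_mean, ag_sd,
#'   flow_class, ordered by decreasing fi_mean.
#' @examples
#' m <- data.frame(sample = rep(c("unmilled", "milled"), each = 3),
#'     fi = c(28.1, 28.5, 28.4, 15.2, 15.8, 15.6),
#'     ag = c(0.05, 0.04, 0.06, 0.42, 0.40, 0.44))
#' rankReport(m)
#' @export
rankReport <- function(measurements, bands = flowBands()) {
    stopifnot(is.data.frame(measurements),
        all(c("sample", "fi") %in% names(measurements)))
    if (nrow(measurements) == 0L) stop("no measurements supplied")
    if (!"ag" %in% names(measurements)) measurements$ag <- NA_real_
    samples <- unique(measurements$sample)   # insertion order
    rows <- lapply(samples, function(s) {
        sub <- measurements[measurements$sample == s, , drop = FALSE]
        fiStats <- summarizeReplicates(sub$fi)
        agStats <- if (all(is.na(sub$ag)))
            list(mean = NA_real_, sd = NA_real_, n = nrow(sub))
        else summarizeReplicates(sub$ag)
        data.frame(sample = s, n = fiStats$n,
            fi_mean = fiStats$mean, fi_sd = fiStats$sd,
            ag_mean = agStats$mean, ag_sd = agStats$sd,
            stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
    report$flow_class <- as.character(classifyFlow(report$fi_mean, bands))
    # stable sort: ties keep insertion order
    report <- report[order(-report$fi_mean), , drop = FALSE]
    rownames(report) <- NULL
    report
}
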