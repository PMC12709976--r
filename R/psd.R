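#' @include AllClasses.R
NULL

# Cumulative volume curve of a distribution: class values are bin upper
# edges; the curve starts at 0 at a lower anchor edge extrapolated with the
# spacing of the first two classes (log-spaced by default, matching
# laser-diffraction size tables).
.cumulativeCurve <- function(dist, interp = c("log", "linear")) {
    interp <- match.arg(interp)
    s <- dist@size
    FF <- cumsum(dist@fraction)
    if (length(s) == 1L)
        return(list(x = s, F = 1, interp = interp))
    anchor <- if (interp == "log") s[1]^2 / s[2] else max(2 * s[1] - s[2], s[1] / 2)
    list(x = c(anchor, s), F = c(0, FF), interp = interp)
}

#' Volume-weighted size percentile (Dv)
#'
#' Returns the size at which the cumulative normalised volume first reaches
#' the fraction `p`, interpolating linearly in log(size) between bracketing
#' class edges (laser-diffraction size classes are log-spaced); linear-in-
#' size interpolation is available via `interp`.
#'
#' @param dist a [SizeDistribution-class].
#' @param p volume fraction in (0, 1); `p = 0.5` gives Dv50.
#' @param interp "log" (default) or "linear" interpolation in size.
#' @return size in micrometres.
#' @examples
#' d <- SizeDistribution(c(10, 100), c(0.5, 0.5))
#' dvPercentile(d, 0.5)  # 10: the cumulative curve first reaches 50% there
#' @export
dvPercentile <- function(dist, p, interp = c("log", "linear")) {
    stopifnot(is(dist, "SizeDistribution"))
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
        stop("p must lie strictly inside (0, 1)")
    cc <- .cumulativeCurve(dist, interp)
    if (length(cc$x) == 1L) return(rep(cc$x, length(p)))
    xs <- if (cc$interp == "log") log(cc$x) else cc$x
    FF <- cc$F
    # invert the piecewise-linear cumulative curve: the smallest size at
    # which it reaches p. When p falls exactly on a flat (zero-weight)
    # segment the first point of the run is taken; otherwise interpolate
    # within the bracketing bin.
    out <- vapply(p, function(pp) {
        i <- which(FF >= pp)[1L]
        if (FF[i] == pp || i == 1L) return(xs[i])
        xs[i - 1L] + (pp - FF[i - 1L]) / (FF[i] - FF[i - 1L]) *
            (xs[i] - xs[i - 1L])
    }, numeric(1))
    if (cc$interp == "log") exp(out) else out
}

#' Distribution span
#'
#' The standard laser-diffraction width measure
#' (Dv90 - Dv10) / Dv50, dimensionless.
#'
#' @param dv10,dv50,dv90 size percentiles in micrometres.
#' @return span value.
#' @examples
#' psdSpan(21.86, 148.50, 556.65)  # 3.60
#' psdSpan(2.07, 38.74, 129.28)    # 3.28
#' @export
psdSpan <- function(dv10, dv50, dv90) {
    if (any(dv50 <= 0)) stop("Dv50 must be positive")
    if (any(dv10 > dv90)) stop("Dv10 must not exceed Dv90")
    (dv90 - dv10) / dv50
}

#' Percentile summary of one size distribution
#'
#' @param dist a [SizeDistribution-class].
#' @param interp interpolation mode, see [dvPercentile()].
#' @return A [PsdSummary-class] with Dv10, Dv50, Dv90 and span.
#' @export
psdSummary <- function(dist, interp = c("log", "linear")) {
    dv <- dvPercentile(dist, c(0.1, 0.5, 0.9), interp)
    new("PsdSummary", dv10 = dv[1], dv50 = dv[2], dv90 = dv[3],
        span = psdSpan(dv[1], dv[2], dv[3]))
}

#' Replicate PSD summary
#'
#' Computes Dv10/Dv50/Dv90 and span per replicate, then aggregates each
#' field across replicates as mean and sample standard deviation (the span
#' is computed per replicate and then averaged, not recomputed from
#' averaged percentiles). Single replicates report NA standard deviations.
#'
#' @param dists list of [SizeDistribution-class] replicates (>= 1).
#' @param interp interpolation mode, see [dvPercentile()].
#' @return data.frame: metric (dv10/dv50/dv90/span), mean, sd, n.
#' @examples
#' d <- SizeDistribution(c(10, 50, 200), c(0.2, 0.5, 0.3))
#' summarizePsd(list(d, d, d))
#' @export
summarizePsd <- function(dists, interp = c("log", "linear")) {
    if (is(dists, "SizeDistribution")) dists <- list(dists)
    if (length(dists) == 0L) stop("at least one replicate is required")
    per <- vapply(dists, function(d) {
        s <- psdSummary(d, interp)
        c(dv10 = s@dv10, dv50 = s@dv50, dv90 = s@dv90, span = s@span)
    }, numeric(4))
    per <- matrix(per, nrow = 4,
        dimnames = list(c("dv10", "dv50", "dv90", "span"), NULL))
    stats <- apply(per, 1, summarizeReplicates)
    data.frame(metric = rownames(per),
        mean = vapply(stats, `[[`, numeric(1), "mean"),
        sd = vapply(stats, `[[`, numeric(1), "sd"),
        n = vapply(stats, `[[`, numeric(1), "n"),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Read size distributions from CSV
#'
#' Expects a header with columns `size_um` and `volume_fraction`, and an
#' optional `replicate` column; without it the file is one replicate.
#' Sizes must be strictly increasing within a replicate.
#'
#' @param path CSV file path.
#' @return list of [SizeDistribution-class], one per replicate.
#' @export
readPsdCsv <- function(path) {
    if (!file.exists(path)) stop("cannot read PSD file: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("size_um", "volume_fraction")
    if (!all(need %in% names(tab)))
        stop("PSD CSV must have columns size_um and volume_fraction: ", path)
    split_by <- if ("replicate" %in% names(tab)) tab$replicate else
        rep(1L, nrow(tab))
    lapply(split(tab, split_by), function(sub) {
        tryCatch(SizeDistribution(sub$size_um, sub$volume_fraction),
            error = function(e) stop("invalid size table in ", path, ": ",
                conditionMessage(e), call. = FALSE))
    })
}
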