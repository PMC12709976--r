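#' @include AllClasses.R
NULL

#' Pixel data of an image or mask
#' @param x a GrayImage or RegionMask
#' @return the underlying matrix (integer intensities or logical members)
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname pixelData
setMethod("pixelData", "GrayImage", function(x) x@pixels)

#' @rdname pixelData
setMethod("pixelData", "RegionMask", function(x) x@members)

#' @describeIn GrayImage-class image dimensions as c(height, width)
#' @param x object
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @describeIn RegionMask-class mask dimensions as c(height, width)
#' @param x object
#' @export
setMethod("dim", "RegionMask", function(x) dim(x@members))

#' Declared bit depth of an image
#' @param x a GrayImage
#' @return 8 or 16
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname bitDepth
setMethod("bitDepth", "GrayImage", function(x) x@bitDepth)

#' Number of member pixels of a mask
#' @param x a RegionMask
#' @return count of TRUE pixels
#' @export
setGeneric("maskSize", function(x) standardGeneric("maskSize"))

#' @rdname maskSize
setMethod("maskSize", "RegionMask", function(x) sum(x@members))

#' Flow Index
#'
#' For a pair of masks, the Flow Index in percent: 100 x |powder| / |roi|.
#' For a [FlowMeasurement-class], the stored FI.
#'
#' @param x a powder RegionMask, or a FlowMeasurement
#' @param roi the region-of-interest RegionMask (mask form only)
#' @return FI in [0, 100]
#' @examples
#' roi <- RegionMask(matrix(TRUE, 100, 100))
#' powder <- RegionMask(matrix(seq_len(1e4) <= 2835, 100, 100))
#' flowIndex(powder, roi)  # 28.35
#' @export
setGeneric("flowIndex", function(x, roi) standardGeneric("flowIndex"))

#' @rdname flowIndex
setMethod("flowIndex", "FlowMeasurement", function(x, roi) x@fiPercent)

#' Agglomeration Ratio stored in a measurement
#' @param x a FlowMeasurement
#' @return AG in [0, 1]
#' @export
setGeneric("agRatio", function(x) standardGeneric("agRatio"))

#' @rdname agRatio
setMethod("agRatio", "FlowMeasurement", function(x) x@agRatio)

#' Ground-truth labels of a synthetic scene
#' @param x a SyntheticScene
#' @return integer matrix: 0 background, 1 dispersed, 2 agglomerate
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))

#' @rdname sceneLabels
setMethod("sceneLabels", "SyntheticScene", function(x) x@labels)

#' Ground-truth FI and AG of a synthetic scene
#' @param x a SyntheticScene
#' @return named numeric c(fi =, ag =)
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname sceneTruth
setMethod("sceneTruth", "SyntheticScene", function(x)
    c(fi = x@truthFi, ag = x@truthAg))

#' Rendered image of a synthetic scene
#' @param x a SyntheticScene
#' @return the GrayImage
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname sceneImage
setMethod("sceneImage", "SyntheticScene", function(x) x@image)

setMethod("show", "GrayImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("GrayImage %d x %d px, %d-bit, intensity range [%d, %d]\n",
        d[2], d[1], object@bitDepth, min(object@pixels), max(object@pixels)))
})

setMethod("show", "RegionMask", function(object) {
    d <- dim(object@members)
    cat(sprintf("RegionMask %d x %d px, %d member pixels (%.1f%%)\n",
        d[2], d[1], sum(object@members),
        100 * mean(object@members)))
})

setMethod("show", "FlowMeasurement", function(object) {
    cat("FlowMeasurement\n")
    cat(sprintf("  Flow Index (FI): %.2f %%  [%g / %g px, %s]\n",
        object@fiPercent, object@powderPixels, object@roiPixels,
        object@polarity))
    cat(sprintf("  Agglomeration Ratio (AG): %.3f  [%s]\n", object@agRatio,
        if (object@bimodal) "bimodal pattern histogram"
        else "pattern histogram judged unimodal"))
    cat(sprintf("  thresholds: powder %s, agglomerate %s\n",
        format(object@powderThreshold), format(object@agglomerateThreshold)))
})

setMethod("show", "SizeDistribution", function(object) {
    cat(sprintf(
        "SizeDistribution: %d classes, %.3g-%.3g um\n",
        length(object@size), min(object@size), max(object@size)))
})

setMethod("show", "PsdSummary", function(object) {
    cat(sprintf(
        "PsdSummary: Dv10 %.2f um, Dv50 %.2f um, Dv90 %.2f um, span %.2f\n",
        object@dv10, object@dv50, object@dv90, object@span))
})

setMethod("show", "SceneParams", function(object) {
    cat(sprintf(
        "SceneParams %d x %d px, coverage %.1f%%, agglomerate fraction %.2f, %s, seed %d\n",
        object@width, object@height, 100 * object@targetCoverage,
        object@agglomerateFraction, object@lighting, object@seed))
})

setMethod("show", "SyntheticScene", function(object) {
    cat(sprintf(
        "SyntheticScene %d x %d px (%s): truth FI %.2f %%, truth AG %.3f, seed %d\n",
        object@params@width, object@params@height, object@params@lighting,
        object@truthFi, object@truthAg, object@params@seed))
})
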