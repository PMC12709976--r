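#' @import methods
NULL

#' GrayImage: a single-channel intensity image
#'
#' Container for a rectangular grid of pixel intensities at a declared bit
#' depth. Pixels are stored as an integer matrix with one row per image row
#' (origin top-left) so that \code{pixels(x)[y + 1, x0 + 1]} is the intensity
#' at 0-based pixel coordinate \code{(x0, y)}. Valid intensities span
#' \code{[0, 2^bitDepth - 1]}.
#'
#' @slot pixels integer matrix of intensities, \code{height x width}.
#' @slot bitDepth integer, 8 or 16.
#'
#' @seealso [GrayImage()], [readFlowImage()], [writeFlowImage()]
#' @exportClass GrayImage
setClass("GrayImage",
    representation(pixels = "matrix", bitDepth = "integer"))

setValidity("GrayImage", function(object) {
    px <- object@pixels
    bd <- object@bitDepth
    if (length(bd) != 1L || !bd %in% c(8L, 16L))
        return("bitDepth must be 8 or 16")
    if (!is.numeric(px) || length(dim(px)) != 2L)
        return("pixels must be a numeric matrix")
    if (nrow(px) < 1L || ncol(px) < 1L)
        return("image must be at least 1 x 1")
    if (anyNA(px))
        return("pixels contain NA")
    if (any(px < 0) || any(px > 2^bd - 1))
        return(sprintf("intensities outside [0, %d]", 2^bd - 1L))
    if (any(px != trunc(px)))
        return("intensities must be integral")
    TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric/integer matrix of intensities (rows = image rows).
#' @param bitDepth 8 (default) or 16.
#' @return A [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(c(0, 64, 128, 255), 2, 2))
#' dim(img)
#' @export
GrayImage <- function(pixels, bitDepth = 8L) {
    storage.mode(pixels) <- "integer"
    new("GrayImage", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' RegionMask: binary per-pixel membership
#'
#' A logical matrix marking pixels belonging to a region (region of
#' interest, powder pattern, agglomerates). Dimensions must match the image
#' the mask annotates.
#'
#' @slot members logical matrix, \code{height x width}.
#' @seealso [RegionMask()], [resolveRoi()], [segmentPowder()]
#' @exportClass RegionMask
setClass("RegionMask", representation(members = "matrix"))

setValidity("RegionMask", function(object) {
    m <- object@members
    if (!is.logical(m) || length(dim(m)) != 2L)
        return("members must be a logical matrix")
    if (nrow(m) < 1L || ncol(m) < 1L)
        return("mask must be at least 1 x 1")
    if (anyNA(m))
        return("mask contains NA")
    TRUE
})

#' Construct a RegionMask
#'
#' @param members logical matrix (rows = image rows).
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(members) {
    if (is.numeric(members)) {
        members <- members != 0
        dim(members) <- dim(members)
    }
    new("RegionMask", members = members)
}

#' IntensityHistogram: 256-bin intensity histogram over a mask
#'
#' Histogram of intensities restricted to a pixel mask. Images of bit depth
#' 16 are binned into 256 bins by integer division of the intensity by 256,
#' so thresholding behaves identically across bit depths; the \code{scale}
#' slot records that bin width (1 for 8-bit, 256 for 16-bit).
#'
#' @slot counts numeric vector of 256 bin counts (bin b holds intensities
#'   \code{[b*scale, (b+1)*scale - 1]} for 0-based bin index b).
#' @slot total total pixel count; equals the member count of the mask the
#'   histogram was taken over.
#' @slot scale intensity width of one bin.
#' @seealso [intensityHistogram()], [otsuThreshold()]
#' @exportClass IntensityHistogram
setClass("IntensityHistogram",
    representation(counts = "numeric", total = "numeric", scale = "numeric"))

setValidity("IntensityHistogram", function(object) {
    if (length(object@counts) != 256L)
        return("counts must have 256 bins")
    if (any(object@counts < 0))
        return("negative bin count")
    if (!isTRUE(all.equal(sum(object@counts), object@total)))
        return("bin counts do not sum to total")
    TRUE
})

#' FlowMeasurement: per-image flowability readout
#'
#' The result of analysing one flow-pattern image: the Flow Index (FI, in
#' percent of the region of interest occupied by powder), the Agglomeration
#' Ratio (AG, fraction of the powder pattern occupied by darker cohesive
#' material, in [0, 1]), the Otsu thresholds used for each, the resolved
#' lighting polarity, a bimodality flag for the within-pattern histogram,
#' and the underlying pixel counts.
#'
#' @slot fiPercent Flow Index in [0, 100].
#' @slot agRatio Agglomeration Ratio in [0, 1].
#' @slot powderThreshold intensity cut separating powder from background
#'   (NA when the ROI histogram was degenerate).
#' @slot agglomerateThreshold intensity cut separating agglomerates from
#'   dispersed powder (NA when no bimodal split was found).
#' @slot polarity "backlight" or "frontlight" (as resolved).
#' @slot bimodal TRUE when the within-pattern histogram passed the
#'   bimodality gate and AG was computed from the dark class.
#' @slot powderPixels number of powder pixels after small-component removal.
#' @slot roiPixels number of pixels in the region of interest.
#' @seealso [analyzeImage()]
#' @exportClass FlowMeasurement
setClass("FlowMeasurement",
    representation(fiPercent = "numeric", agRatio = "numeric",
        powderThreshold = "numeric", agglomerateThreshold = "numeric",
        polarity = "character", bimodal = "logical",
        powderPixels = "numeric", roiPixels = "numeric"))

setValidity("FlowMeasurement", function(object) {
    if (object@fiPercent < 0 || object@fiPercent > 100)
        return("fiPercent outside [0, 100]")
    if (object@agRatio < 0 || object@agRatio > 1)
        return("agRatio outside [0, 1]")
    if (object@powderPixels > object@roiPixels)
        return("powder pixel count exceeds ROI pixel count")
    if (!object@polarity %in% c("backlight", "frontlight"))
        return("polarity must be backlight or frontlight")
    if (object@roiPixels > 0) {
        fi <- 100 * object@powderPixels / object@roiPixels
        if (abs(fi - object@fiPercent) > 1e-8)
            return("fiPercent inconsistent with pixel counts")
    }
    TRUE
})

#' SizeDistribution: a volume-weighted particle size distribution
#'
#' One laser-diffraction-style size table: strictly increasing size classes
#' (treated as bin upper edges of a cumulative curve starting at zero) and
#' nonnegative volume fractions, normalised internally to sum to one.
#'
#' @slot size particle size class values in micrometres, strictly increasing.
#' @slot fraction normalised volume fraction per class.
#' @seealso [SizeDistribution()], [dvPercentile()], [summarizePsd()]
#' @exportClass SizeDistribution
setClass("SizeDistribution",
    representation(size = "numeric", fraction = "numeric"))

setValidity("SizeDistribution", function(object) {
    s <- object@size; w <- object@fraction
    if (length(s) < 1L) return("at least one size class required")
    if (length(s) != length(w)) return("size and fraction lengths differ")
    if (anyNA(s) || anyNA(w)) return("NA in size table")
    if (any(s <= 0)) return("sizes must be positive")
    if (is.unsorted(s, strictly = TRUE)) return("sizes must be strictly increasing")
    if (any(w < 0)) return("volume fractions must be nonnegative")
    if (!isTRUE(all.equal(sum(w), 1)))
        return("fractions must be normalised (use the constructor)")
    TRUE
})

#' Construct a SizeDistribution
#'
#' @param size numeric vector of size class values (um), strictly increasing.
#' @param fraction nonnegative volume weights; normalised to sum to 1.
#' @return A [SizeDistribution-class].
#' @examples
#' d <- SizeDistribution(c(10, 100), c(1, 1))
#' dvPercentile(d, 0.5)
#' @export
SizeDistribution <- function(size, fraction) {
    tot <- sum(fraction)
    if (!is.finite(tot) || tot <= 0)
        stop("volume fractions must sum to a positive total")
    new("SizeDistribution", size = as.numeric(size),
        fraction = as.numeric(fraction) / tot)
}

#' PsdSummary: Dv percentiles and span for one sample
#'
#' @slot dv10,dv50,dv90 volume-weighted size percentiles in micrometres.
#' @slot span dimensionless width, (Dv90 - Dv10) / Dv50.
#' @seealso [psdSummary()], [psdSpan()]
#' @exportClass PsdSummary
setClass("PsdSummary",
    representation(dv10 = "numeric", dv50 = "numeric", dv90 = "numeric",
        span = "numeric"))

setValidity("PsdSummary", function(object) {
    if (!(object@dv10 <= object@dv50 && object@dv50 <= object@dv90))
        return("percentiles must satisfy dv10 <= dv50 <= dv90")
    if (object@span < 0) return("span must be nonnegative")
    expected <- (object@dv90 - object@dv10) / object@dv50
    if (abs(expected - object@span) > 1e-8)
        return("span inconsistent with percentiles")
    TRUE
})

#' SceneParams: parameters of a synthetic flow-pattern scene
#'
#' Describes one synthetic backlit/frontlit flow pattern: frame size, the
#' target area coverage of the region of interest, the target fraction of
#' covered area belonging to cohesive agglomerates, particle and cluster
#' geometry laws, the intensity model and noise, and the seed.
#'
#' Dispersed particles are disks from a homogeneous point process with
#' lognormal radii; agglomerates are parent-offspring (Thomas-type)
#' clusters of such disks. Rendering: background at
#' \code{backgroundLevel}; pixels covered by dispersed powder at
#' \code{particleLevel} (a flowing monolayer); pixels covered by m
#' cluster-member disks at \code{agglomerateLevel * exp(-kappa * (m - 1))}
#' (stacked, optically thicker material), then Gaussian noise and clipping.
#'
#' @slot width,height frame size in pixels.
#' @slot targetCoverage fraction of the frame to cover with powder, in (0,1).
#' @slot agglomerateFraction target fraction of covered area belonging to
#'   agglomerates, in [0,1].
#' @slot radiusMedian,radiusShape lognormal disk-radius law (median px,
#'   log-sd); radii are clamped to a 2 px minimum so particles survive
#'   rasterisation.
#' @slot clusterMeanSize mean number of member disks per agglomerate cluster.
#' @slot clusterRadius isotropic Gaussian spread of cluster offspring (px).
#' @slot lighting "backlight" or "frontlight".
#' @slot backgroundLevel,particleLevel,agglomerateLevel gray levels of the
#'   illuminated background, a powder monolayer, and a single agglomerate
#'   layer (8-bit scale).
#' @slot kappa extra attenuation per additional overlapping cluster disk.
#' @slot noiseSd Gaussian noise standard deviation in gray levels.
#' @slot seed integer seed; identical params give byte-identical scenes.
#' @slot maxAttempts placement attempts before an unreachable-coverage error.
#' @seealso [sceneParams()], [generateScene()]
#' @exportClass SceneParams
setClass("SceneParams",
    representation(width = "integer", height = "integer",
        targetCoverage = "numeric", agglomerateFraction = "numeric",
        radiusMedian = "numeric", radiusShape = "numeric",
        clusterMeanSize = "numeric", clusterRadius = "numeric",
        lighting = "character",
        backgroundLevel = "numeric", particleLevel = "numeric",
        agglomerateLevel = "numeric", kappa = "numeric",
        noiseSd = "numeric", seed = "integer", maxAttempts = "integer"))

setValidity("SceneParams", function(object) {
    if (object@width < 8L || object@height < 8L)
        return("frame must be at least 8 x 8")
    if (object@targetCoverage <= 0 || object@targetCoverage >= 1)
        return("targetCoverage must lie in (0, 1)")
    if (object@agglomerateFraction < 0 || object@agglomerateFraction > 1)
        return("agglomerateFraction must lie in [0, 1]")
    lv <- c(object@backgroundLevel, object@particleLevel, object@agglomerateLevel)
    if (any(lv < 0) || any(lv > 255))
        return("intensity levels must lie in [0, 255]")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    if (!object@lighting %in% c("backlight", "frontlight"))
        return("lighting must be backlight or frontlight")
    TRUE
})

#' SyntheticScene: a rendered scene with per-pixel ground truth
#'
#' @slot image the rendered [GrayImage-class].
#' @slot labels integer matrix: 0 background, 1 dispersed, 2 agglomerate.
#' @slot truthFi ground-truth Flow Index: 100 x covered pixels / frame pixels.
#' @slot truthAg ground-truth Agglomeration Ratio: agglomerate pixels /
#'   covered pixels.
#' @slot params the [SceneParams-class] that generated the scene.
#' @seealso [generateScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
    representation(image = "GrayImage", labels = "matrix",
        truthFi = "numeric", truthAg = "numeric", params = "SceneParams"))

setValidity("SyntheticScene", function(object) {
    if (!identical(dim(object@labels), dim(object@image@pixels)))
        return("labels and image dimensions differ")
    if (!all(object@labels %in% 0:2))
        return("labels must be 0 (background), 1 (dispersed) or 2 (agglomerate)")
    covered <- sum(object@labels > 0L)
    fi <- 100 * covered / length(object@labels)
    if (abs(fi - object@truthFi) > 1e-8)
        return("truthFi inconsistent with label map")
    ag <- if (covered > 0) sum(object@labels == 2L) / covered else 0
    if (abs(ag - object@truthAg) > 1e-8)
        return("truthAg inconsistent with label map")
    TRUE
})
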