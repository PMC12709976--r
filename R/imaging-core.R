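#' @include AllClasses.R
NULL

.checkSameDim <- function(image, mask) {
    if (!identical(dim(image@pixels), dim(mask@members)))
        stop("mask dimensions (", paste(dim(mask@members), collapse = " x "),
            ") do not match image (",
            paste(dim(image@pixels), collapse = " x "), ")")
}

#' Intensity histogram over a mask
#'
#' Counts intensities of the pixels where the mask is set, into 256 bins.
#' 16-bit images are binned by integer division of the intensity by 256 so
#' that downstream thresholding is bit-depth independent.
#'
#' @param image a [GrayImage-class].
#' @param mask a [RegionMask-class] of matching dimensions; defaults to the
#'   full frame.
#' @return An [IntensityHistogram-class] whose total equals the mask member
#'   count.
#' @examples
#' img <- GrayImage(matrix(c(50, 50, 200, 200), 2, 2))
#' intensityHistogram(img)
#' @export
intensityHistogram <- function(image, mask = fullFrameMask(image)) {
    stopifnot(is(image, "GrayImage"), is(mask, "RegionMask"))
    .checkSameDim(image, mask)
    scale <- 2^(image@bitDepth - 8L)
    vals <- image@pixels[mask@members]
    bins <- vals %/% scale
    counts <- tabulate(bins + 1L, nbins = 256L)
    new("IntensityHistogram", counts = as.numeric(counts),
        total = as.numeric(length(vals)), scale = as.numeric(scale))
}

#' Full-frame mask for an image
#'
#' @param image a [GrayImage-class].
#' @return A [RegionMask-class] covering every pixel.
#' @export
fullFrameMask <- function(image) {
    RegionMask(matrix(TRUE, nrow(image@pixels), ncol(image@pixels)))
}

#' Resolve a region-of-interest specification
#'
#' The ROI plays the role of the total illuminated background area in the
#' Flow Index denominator. Accepted specifications: `NULL` (full frame), a
#' rectangle `c(x0, y0, w, h)` in 0-based pixel coordinates (half-open,
#' clipped to the frame), or an explicit [RegionMask-class] which is passed
#' through after a dimension check.
#'
#' @param image a [GrayImage-class].
#' @param roiSpec `NULL`, a length-4 numeric rectangle, or a RegionMask.
#' @return A [RegionMask-class].
#' @examples
#' img <- GrayImage(matrix(0L, 80, 100))
#' maskSize(resolveRoi(img))                      # 8000
#' maskSize(resolveRoi(img, c(0, 0, 10, 10)))     # 100
#' @export
resolveRoi <- function(image, roiSpec = NULL) {
    stopifnot(is(image, "GrayImage"))
    h <- nrow(image@pixels); w <- ncol(image@pixels)
    if (is.null(roiSpec))
        return(fullFrameMask(image))
    if (is(roiSpec, "RegionMask")) {
        .checkSameDim(image, roiSpec)
        return(roiSpec)
    }
    if (is.numeric(roiSpec) && length(roiSpec) == 4L) {
        x0 <- roiSpec[1]; y0 <- roiSpec[2]
        rw <- roiSpec[3]; rh <- roiSpec[4]
        if (rw < 0 || rh < 0) stop("ROI rectangle has negative extent")
        # half-open [x0, x0+w) x [y0, y0+h), clipped to the frame
        xs <- max(0, x0); xe <- min(w, x0 + rw)
        ys <- max(0, y0); ye <- min(h, y0 + rh)
        if (xs >= xe || ys >= ye)
            stop("ROI rectangle lies fully outside the frame")
        m <- matrix(FALSE, h, w)
        m[(ys + 1):ye, (xs + 1):xe] <- TRUE
        return(RegionMask(m))
    }
    stop("roiSpec must be NULL, c(x0, y0, w, h), or a RegionMask")
}

#' Parse an ROI string
#'
#' Turns the command-line form `"x0,y0,w,h"` into a rectangle vector, or a
#' mask-image path into a [RegionMask-class] (nonzero pixels are members).
#'
#' @param spec a string: either four comma-separated integers or a path to
#'   a mask image.
#' @return A numeric rectangle or a RegionMask, suitable for [resolveRoi()].
#' @export
parseRoiSpec <- function(spec) {
    if (is.null(spec) || !nzchar(spec)) return(NULL)
    if (grepl("^ *-?[0-9]+ *(, *-?[0-9]+ *){3}$", spec))
        return(as.numeric(strsplit(spec, ",")[[1]]))
    img <- readFlowImage(spec)
    RegionMask(img@pixels > 0L)
}
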