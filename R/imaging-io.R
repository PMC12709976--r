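#' @include AllClasses.R
NULL

# Rec. 709 luminance weights for RGB -> gray conversion. Any convex
# weighting maps equal channels to the channel value; 709 matches typical
# digital camera output.
.LUMA <- c(0.2126, 0.7152, 0.0722)

.fileMagic <- function(path) {
    sig <- readBin(path, "raw", 8L)
    if (length(sig) >= 8L &&
        identical(sig[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47))))
        return("png")
    if (length(sig) >= 4L &&
        (identical(sig[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
         identical(sig[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a)))))
        return("tiff")
    "unknown"
}

# PNG IHDR: byte 25 = bit depth (per channel), byte 26 = color type.
.pngBitDepth <- function(path) {
    hdr <- readBin(path, "raw", 26L)
    if (length(hdr) < 26L) stop("truncated PNG header: ", path)
    as.integer(hdr[25L])
}

.collapseChannels <- function(arr, maxval) {
    if (length(dim(arr)) == 2L) return(arr)
    nc <- dim(arr)[3L]
    if (nc == 1L) return(arr[, , 1L])
    if (nc %in% c(3L, 4L)) {
        # alpha, if present, is ignored
        g <- .LUMA[1L] * arr[, , 1L] + .LUMA[2L] * arr[, , 2L] +
            .LUMA[3L] * arr[, , 3L]
        return(g)
    }
    stop("unsupported channel layout: ", nc, " channels")
}

#' Read a flow-pattern image from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale image; RGB inputs are converted to
#' luminance with Rec. 709 weights. 16-bit inputs keep their bit depth.
#'
#' @param path path to a PNG or TIFF file.
#' @return A [GrayImage-class].
#' @examples
#' tf <- tempfile(fileext = ".png")
#' writeFlowImage(GrayImage(matrix(c(0, 64, 128, 255), 2, 2)), tf)
#' readFlowImage(tf)
#' @export
readFlowImage <- function(path) {
    if (!file.exists(path))
        stop("cannot read image file: ", path)
    kind <- .fileMagic(path)
    if (kind == "png") {
        depth <- .pngBitDepth(path)
        if (!depth %in% c(8L, 16L))
            stop("unsupported PNG bit depth ", depth, ": ", path)
        arr <- png::readPNG(path)              # scaled to [0, 1]
        maxval <- 2^depth - 1L
        g <- round(.collapseChannels(arr, maxval) * maxval)
    } else if (kind == "tiff") {
        arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
        depth <- attr(arr, "bits.per.sample")
        if (is.null(depth)) depth <- if (max(arr) > 255) 16L else 8L
        if (!depth %in% c(8L, 16L))
            stop("unsupported TIFF bit depth ", depth, ": ", path)
        g <- round(.collapseChannels(arr, 2^depth - 1L))
    } else {
        stop("not a PNG or TIFF file: ", path)
    }
    g <- matrix(as.integer(g), nrow(g), ncol(g))  # drop reader metadata
    GrayImage(g, bitDepth = as.integer(depth))
}

#' Write a GrayImage to PNG or TIFF
#'
#' The format follows the file extension (.png, .tif/.tiff). 16-bit images
#' must be written as TIFF. Round-trips through [readFlowImage()] are
#' pixel-exact.
#'
#' @param image a [GrayImage-class].
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeFlowImage <- function(image, path) {
    stopifnot(is(image, "GrayImage"))
    maxval <- 2^image@bitDepth - 1
    x <- image@pixels / maxval
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        if (image@bitDepth != 8L)
            stop("PNG output supports 8-bit images only; use TIFF for 16-bit")
        png::writePNG(x, path)
    } else if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(x, path, bits.per.sample = image@bitDepth,
            compression = "none")
    } else {
        stop("unsupported output extension: .", ext)
    }
    invisible(path)
}
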