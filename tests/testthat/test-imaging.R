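test_that("PNG and TIFF round-trips reproduce every pixel exactly", {
    set.seed(11)
    img8 <- GrayImage(matrix(sample(0:255, 400, replace = TRUE), 20, 20))
    for (ext in c(".png", ".tif")) {
        tf <- withr::local_tempfile(fileext = ext)
        writeFlowImage(img8, tf)
        back <- readFlowImage(tf)
        expect_identical(pixelData(back), pixelData(img8))
        expect_identical(bitDepth(back), 8L)
    }
    img16 <- GrayImage(matrix(sample(0:65535, 400, replace = TRUE), 20, 20),
        bitDepth = 16L)
    tf <- withr::local_tempfile(fileext = ".tiff")
    writeFlowImage(img16, tf)
    back <- readFlowImage(tf)
    expect_identical(pixelData(back), pixelData(img16))
    expect_identical(bitDepth(back), 16L)
})

test_that("the worked 2x2 example and error paths behave as documented", {
    img <- GrayImage(matrix(c(0L, 64L, 128L, 255L), 2, 2))
    tf <- withr::local_tempfile(fileext = ".png")
    writeFlowImage(img, tf)
    expect_identical(sort(as.vector(pixelData(readFlowImage(tf)))),
        c(0L, 64L, 128L, 255L))
    expect_error(readFlowImage("no/such/file.png"), "no/such/file.png")
    junk <- withr::local_tempfile(fileext = ".png")
    writeLines("not an image", junk)
    expect_error(readFlowImage(junk), "PNG or TIFF")
    expect_error(writeFlowImage(GrayImage(matrix(0L, 2, 2), 16L),
        withr::local_tempfile(fileext = ".png")), "16-bit")
})

test_that("RGB inputs convert to luminance: equal channels map to the channel value", {
    arr <- array(0, c(2, 2, 3))
    arr[1, 1, ] <- 1               # white -> 255
    arr[1, 2, ] <- 100 / 255       # equal channels -> 100
    arr[2, 1, ] <- c(30, 200, 90) / 255
    tf <- withr::local_tempfile(fileext = ".png")
    png::writePNG(arr, tf)
    g <- readFlowImage(tf)
    expect_identical(pixelData(g)[1, 1], 255L)
    expect_identical(pixelData(g)[1, 2], 100L)
    # luminance is monotone: raising a channel never lowers it
    arr2 <- arr
    arr2[2, 1, 2] <- 220 / 255
    tf2 <- withr::local_tempfile(fileext = ".png")
    png::writePNG(arr2, tf2)
    expect_gte(pixelData(readFlowImage(tf2))[2, 1], pixelData(g)[2, 1])
})

test_that("histograms count masked pixels only and conserve totals over mask splits", {
    img <- GrayImage(matrix(7L, 10, 10))
    h <- intensityHistogram(img)
    expect_equal(h@counts[8], 100)
    expect_equal(sum(h@counts), 100)

    # {10 x 50, 30 x 200} under a full mask
    img2 <- GrayImage(matrix(c(rep(50L, 10), rep(200L, 30)), 4, 10))
    h2 <- intensityHistogram(img2)
    expect_equal(h2@counts[51], 10)
    expect_equal(h2@counts[201], 30)

    # empty mask -> total 0
    empty <- RegionMask(matrix(FALSE, 4, 10))
    expect_equal(intensityHistogram(img2, empty)@total, 0)

    # splitting a mask into disjoint parts sums to the union histogram
    set.seed(21)
    img3 <- GrayImage(matrix(sample(0:255, 600, replace = TRUE), 20, 30))
    sel <- matrix(runif(600) < 0.6, 20, 30)
    part <- matrix(runif(600) < 0.5, 20, 30)
    a <- intensityHistogram(img3, RegionMask(sel & part))
    b <- intensityHistogram(img3, RegionMask(sel & !part))
    u <- intensityHistogram(img3, RegionMask(sel))
    expect_equal(a@counts + b@counts, u@counts)
    expect_equal(a@total + b@total, u@total)

    expect_error(intensityHistogram(img2, RegionMask(matrix(TRUE, 3, 3))),
        "dimensions")
})

test_that("16-bit histograms bin by intensity %/% 256", {
    px <- matrix(c(0L, 255L, 256L, 65535L), 2, 2)
    h <- intensityHistogram(GrayImage(px, 16L))
    expect_equal(h@counts[1], 2)    # 0 and 255 share bin 0
    expect_equal(h@counts[2], 1)    # 256 -> bin 1
    expect_equal(h@counts[256], 1)  # 65535 -> bin 255
    expect_equal(h@scale, 256)
})

test_that("ROI resolution covers full-frame, rectangle, clipping and mask pass-through", {
    img <- GrayImage(matrix(0L, 80, 100))
    expect_equal(maskSize(resolveRoi(img)), 8000)
    expect_equal(maskSize(resolveRoi(img, c(0, 0, 10, 10))), 100)
    # rectangle half outside: area of intersection
    expect_equal(maskSize(resolveRoi(img, c(95, 0, 10, 10))), 50)
    expect_equal(maskSize(resolveRoi(img, c(-5, -5, 10, 10))), 25)
    expect_error(resolveRoi(img, c(200, 200, 10, 10)), "outside")
    m <- RegionMask(matrix(c(TRUE, FALSE), 80, 100))
    expect_identical(resolveRoi(img, m), m)
    expect_error(resolveRoi(img, RegionMask(matrix(TRUE, 2, 2))),
        "dimensions")
})

test_that("ROI string parsing handles rectangles and mask image paths", {
    expect_equal(parseRoiSpec("0,0,10,10"), c(0, 0, 10, 10))
    expect_null(parseRoiSpec(""))
    tf <- withr::local_tempfile(fileext = ".png")
    mpx <- matrix(0L, 6, 6); mpx[2:4, 2:4] <- 255L
    writeFlowImage(GrayImage(mpx), tf)
    rm <- parseRoiSpec(tf)
    expect_s4_class(rm, "RegionMask")
    expect_equal(maskSize(rm), 9)
})

test_that("class validity rejects malformed objects", {
    expect_error(GrayImage(matrix(-1L, 2, 2)), "intensities")
    expect_error(GrayImage(matrix(256L, 2, 2), 8L), "intensities")
    expect_error(new("GrayImage", pixels = matrix(0L, 2, 2), bitDepth = 12L),
        "bitDepth")
    expect_error(new("FlowMeasurement", fiPercent = 50, agRatio = 0,
        powderThreshold = NA_real_, agglomerateThreshold = NA_real_,
        polarity = "backlight", bimodal = FALSE, powderPixels = 10,
        roiPixels = 100), "inconsistent")
})
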