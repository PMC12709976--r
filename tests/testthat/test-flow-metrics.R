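test_that("Otsu threshold matches the brute-force between-class-variance maximiser", {
    # two spikes: any cut between them separates the classes; the
    # implementation must return the brute-force maximiser
    counts <- numeric(256); counts[51] <- 50; counts[201] <- 50
    t <- otsuThreshold(histFromCounts(counts))
    expect_gte(t, 50); expect_lte(t, 199)
    expect_identical(t, as.numeric(bruteForceOtsu(counts)))

    set.seed(42)
    for (i in 1:120) {
        counts <- randomHistogram()
        expect_identical(otsuThreshold(histFromCounts(counts)),
            as.numeric(bruteForceOtsu(counts)))
    }

    single <- numeric(256); single[100] <- 40
    expect_error(otsuThreshold(histFromCounts(single)), "degenerate")
})

test_that("Otsu threshold for 16-bit histograms is reported on the intensity scale", {
    px <- matrix(c(rep(1000L, 20), rep(60000L, 20)), 4, 10)
    h <- intensityHistogram(GrayImage(px, 16L))
    t <- otsuThreshold(h)
    expect_true(t >= 1000 && t < 60000)
    expect_equal((t + 1) %% 256, 0)  # top of a 256-wide bin
})

test_that("powder segmentation separates the dark/bright classes by polarity", {
    # backlit: 70% illumination at 230, 30% powder at 60
    img <- bandFixture(100, coverage = 0.3, powder = 60L)
    roi <- fullFrameMask(img)
    powder <- segmentPowder(img, roi, "backlight")
    expect_equal(maskSize(powder), 3000)
    expect_true(all(pixelData(img)[pixelData(powder)] == 60L))

    # frontlit: symmetric under intensity inversion
    inv <- GrayImage(255L - pixelData(img))
    front <- segmentPowder(inv, roi, "frontlight")
    expect_identical(pixelData(front), pixelData(powder))

    # uniform bright ROI: empty mask with a warning, not an exception
    flat <- GrayImage(matrix(230L, 50, 50))
    expect_warning(out <- segmentPowder(flat, fullFrameMask(flat),
        "backlight"), "degenerate")
    expect_equal(maskSize(out), 0)
    expect_true(attr(out, "degenerate"))
})

test_that("auto polarity picks backlight for bright borders and frontlight for dark", {
    img <- bandFixture(100, coverage = 0.3, powder = 60L)  # bright border
    auto <- segmentPowder(img, fullFrameMask(img), "auto")
    expect_identical(attr(auto, "polarity"), "backlight")
    inv <- GrayImage(255L - pixelData(img))
    autoInv <- segmentPowder(inv, fullFrameMask(inv), "auto")
    expect_identical(attr(autoInv, "polarity"), "frontlight")
    expect_identical(pixelData(autoInv), pixelData(auto))
})

test_that("flow index is the powder area percentage of the ROI", {
    roi <- RegionMask(matrix(TRUE, 100, 100))
    none <- RegionMask(matrix(FALSE, 100, 100))
    expect_equal(flowIndex(none, roi), 0)
    expect_equal(flowIndex(roi, roi), 100)
    powder <- RegionMask(matrix(seq_len(1e4) <= 2835, 100, 100))
    expect_equal(flowIndex(powder, roi), 28.35)
    expect_error(flowIndex(powder, none), "empty")
    half <- RegionMask(matrix(rep(c(TRUE, FALSE), each = 5000), 100, 100))
    expect_error(flowIndex(roi, half), "subset")
})

test_that("FI is monotone in the powder mask and invariant under translation", {
    roi <- RegionMask(matrix(TRUE, 50, 50))
    m <- matrix(FALSE, 50, 50); m[10:20, 10:20] <- TRUE
    fi1 <- flowIndex(RegionMask(m), roi)
    m2 <- m; m2[30:35, 30:35] <- TRUE
    expect_gt(flowIndex(RegionMask(m2), roi), fi1)
    # translating the pattern inside the frame leaves FI unchanged
    shifted <- matrix(FALSE, 50, 50); shifted[25:35, 25:35] <- TRUE
    expect_equal(flowIndex(RegionMask(shifted), roi), fi1)
})

test_that("small-component suppression drops specks below the minimum size", {
    m <- matrix(FALSE, 30, 30)
    m[5:10, 5:10] <- TRUE       # 36 px, kept
    m[20, 20] <- TRUE           # 1 px speck, dropped
    m[25, 25:27] <- TRUE        # 3 px speck, dropped
    out <- dropSmallComponents(RegionMask(m), 4L)
    expect_equal(maskSize(out), 36)
    expect_equal(maskSize(dropSmallComponents(RegionMask(m), 1L)), 40)
})

test_that("AG is the dark-class fraction within the powder pattern", {
    # 40% at 60 (agglomerate), 60% at 160 (dispersed)
    px <- matrix(c(rep(60L, 40), rep(160L, 60)), 10, 10)
    img <- GrayImage(px)
    res <- agglomerationRatio(img, fullFrameMask(img))
    expect_equal(res$ag, 0.40)
    expect_true(res$bimodal)
    expect_true(res$threshold >= 60 && res$threshold < 160)
    # dark-class + bright-class fractions sum to one over the pattern
    expect_equal(res$darkPixels / res$powderPixels +
        (res$powderPixels - res$darkPixels) / res$powderPixels, 1)

    # single-intensity pattern: unimodal, AG = 0
    flat <- GrayImage(matrix(160L, 10, 10))
    res0 <- agglomerationRatio(flat, fullFrameMask(flat))
    expect_equal(res0$ag, 0)
    expect_false(res0$bimodal)

    expect_error(agglomerationRatio(img, RegionMask(matrix(FALSE, 10, 10))),
        "empty")
})

test_that("the bimodality gate rejects unimodal noise but accepts separated modes", {
    set.seed(7)
    # a single Gaussian mode must not be declared bimodal
    vals <- pmin(pmax(round(rnorm(2500, 160, 6)), 0), 255)
    img <- GrayImage(matrix(as.integer(vals), 50, 50))
    res <- agglomerationRatio(img, fullFrameMask(img))
    expect_false(res$bimodal)
    expect_equal(res$ag, 0)
    # a uniform spread must not be declared bimodal either
    u <- GrayImage(matrix(as.integer(sample(120:200, 2500, TRUE)), 50, 50))
    resU <- agglomerationRatio(u, fullFrameMask(u))
    expect_false(resU$bimodal)
    # two modes 60 levels apart at modest spread pass the gate
    vals2 <- c(round(rnorm(1000, 100, 5)), round(rnorm(1500, 160, 5)))
    img2 <- GrayImage(matrix(as.integer(pmin(pmax(vals2, 0), 255)), 50, 50))
    res2 <- agglomerationRatio(img2, fullFrameMask(img2))
    expect_true(res2$bimodal)
    expect_lt(abs(res2$ag - 0.4), 0.05)
})

test_that("analyzeImage composes the pipeline on constructed fixtures", {
    # uniform bright image: FI 0, AG 0 (flagged)
    flat <- GrayImage(matrix(230L, 60, 60))
    m0 <- analyzeImage(flat, polarity = "backlight")
    expect_equal(flowIndex(m0), 0)
    expect_equal(agRatio(m0), 0)
    expect_false(m0@bimodal)

    # two-level backlit fixture, 30% coverage, single powder intensity
    m1 <- analyzeImage(bandFixture(100, 0.3), polarity = "backlight")
    expect_equal(flowIndex(m1), 30)
    expect_equal(agRatio(m1), 0)

    # three-level backlit fixture: 30% powder of which 40% agglomerate
    m2 <- analyzeImage(bandFixture(100, 0.3, 0.4), polarity = "backlight")
    expect_equal(flowIndex(m2), 30)
    expect_equal(agRatio(m2), 0.4)
    expect_true(m2@bimodal)
    expect_equal(m2@powderPixels, 3000)
    expect_equal(m2@roiPixels, 10000)
    # determinism for fixed inputs
    expect_identical(m2, analyzeImage(bandFixture(100, 0.3, 0.4),
        polarity = "backlight"))
})

test_that("FI and AG are invariant under non-clipping affine intensity remaps", {
    img <- bandFixture(100, 0.3, 0.4, bg = 115L, powder = 80L, agg = 50L)
    base <- analyzeImage(img, polarity = "backlight")
    remap <- GrayImage(2L * pixelData(img) + 20L)  # strictly increasing, no clip
    after <- analyzeImage(remap, polarity = "backlight")
    expect_equal(flowIndex(after), flowIndex(base))
    expect_equal(agRatio(after), agRatio(base))
    expect_equal(after@powderPixels, base@powderPixels)
})

test_that("polarity inversion symmetry holds on fixtures", {
    for (af in c(0, 0.4)) {
        img <- bandFixture(100, 0.3, af)
        inv <- GrayImage(255L - pixelData(img))
        a <- analyzeImage(img, polarity = "backlight")
        b <- analyzeImage(inv, polarity = "frontlight")
        expect_equal(flowIndex(b), flowIndex(a))
        expect_equal(b@powderPixels, a@powderPixels)
    }
})
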