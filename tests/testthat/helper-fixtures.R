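# Fixture builders and independent oracles shared across tests.

# Backlit band fixture: bright background, a horizontal powder band of
# `coverage` of the frame, of which the leftmost `agFraction` of columns is
# agglomerate. Levels chosen for clean three-way mode separation.
bandFixture <- function(n = 100, coverage = 0.3, agFraction = 0,
        bg = 230L, powder = 160L, agg = 100L) {
    px <- matrix(bg, n, n)
    rows <- seq_len(round(coverage * n))
    band <- rows + round((n - length(rows)) / 2)
    px[band, ] <- powder
    if (agFraction > 0)
        px[band, seq_len(round(agFraction * n))] <- agg
    GrayImage(px)
}

# Histogram object from raw counts (256 bins).
histFromCounts <- function(counts, scale = 1) {
    new("IntensityHistogram", counts = as.numeric(counts),
        total = sum(counts), scale = scale)
}

# Brute-force Otsu oracle: exhaustive search over all 255 cuts, maximising
# between-class variance directly from class moments; lowest maximising cut.
bruteForceOtsu <- function(counts) {
    p <- counts / sum(counts)
    v <- 0:255
    best <- -Inf; bestT <- NA_integer_
    for (t in 0:254) {
        w0 <- sum(p[v <= t])
        if (w0 <= 0 || w0 >= 1) next
        mu0 <- sum(p[v <= t] * v[v <= t]) / w0
        mu1 <- sum(p[v > t] * v[v > t]) / (1 - w0)
        s <- w0 * (1 - w0) * (mu0 - mu1)^2
        if (s > best + 1e-12) { best <- s; bestT <- t }
    }
    bestT
}

# Brute-force Dv oracle: evaluate the interpolated cumulative curve on a
# fine size grid and return the smallest grid size whose cumulative volume
# reaches p.
bruteForceDv <- function(dist, p, interp = "log", gridN = 200000L) {
    s <- dist@size
    FF <- cumsum(dist@fraction)
    if (length(s) == 1L) return(s)
    anchor <- if (interp == "log") s[1]^2 / s[2] else
        max(2 * s[1] - s[2], s[1] / 2)
    xs <- c(anchor, s); Fs <- c(0, FF)
    if (interp == "log") {
        grid <- exp(seq(log(xs[1]), log(xs[length(xs)]), length.out = gridN))
        Fg <- approx(log(xs), Fs, log(grid), ties = "ordered")$y
    } else {
        grid <- seq(xs[1], xs[length(xs)], length.out = gridN)
        Fg <- approx(xs, Fs, grid, ties = "ordered")$y
    }
    grid[which(Fg >= p)[1]]
}

# Random occupied histogram over 256 bins.
randomHistogram <- function() {
    k <- sample(2:30, 1)
    bins <- sort(sample(0:255, k))
    counts <- numeric(256)
    counts[bins + 1] <- sample(1:50, k, replace = TRUE)
    counts
}

expect_scene_recovers <- function(scene, fiTol = 2, agTol = 0.05) {
    m <- analyzeImage(sceneImage(scene),
        polarity = scene@params@lighting)
    tr <- sceneTruth(scene)
    expect_lt(abs(flowIndex(m) - tr[["fi"]]), fiTol)
    expect_lt(abs(agRatio(m) - tr[["ag"]]), agTol)
    invisible(m)
}
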