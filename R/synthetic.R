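#' @include AllClasses.R AllGenerics.R
NULL

#' Construct scene parameters
#'
#' Defaults describe a backlit flow pattern whose gray-level structure
#' satisfies the bimodality assumptions of Otsu-based analysis: background
#' 230, dispersed powder monolayer 160, agglomerate layer 100 (mode
#' separations of 70 and 60 gray levels), with mild extra darkening per
#' stacked cluster disk. Dispersed particles follow a lognormal disk-radius
#' law (median 4 px); agglomerates are Thomas-type clusters of on average
#' 20 member disks spread with a 7 px Gaussian.
#'
#' @param width,height frame size in pixels.
#' @param targetCoverage fraction of the frame to cover, in (0, 1).
#' @param agglomerateFraction fraction of covered area that is
#'   agglomerate, in [0, 1].
#' @param radiusMedian,radiusShape lognormal radius law (median px, log-sd).
#' @param clusterMeanSize mean member disks per cluster.
#' @param clusterRadius Gaussian offspring spread (px).
#' @param lighting "backlight" or "frontlight".
#' @param backgroundLevel,particleLevel,agglomerateLevel gray levels.
#' @param kappa extra attenuation per additional overlapping cluster disk.
#' @param noiseSd Gaussian noise sd in gray levels.
#' @param seed integer seed.
#' @param maxAttempts placement attempts before giving up.
#' @return A [SceneParams-class].
#' @examples
#' sceneParams(targetCoverage = 0.3, agglomerateFraction = 0.4, seed = 7)
#' @export
sceneParams <- function(width = 512L, height = 512L,
        targetCoverage = 0.30, agglomerateFraction = 0,
        radiusMedian = 4, radiusShape = 0.25,
        clusterMeanSize = 20, clusterRadius = 7,
        lighting = c("backlight", "frontlight"),
        backgroundLevel = 230, particleLevel = 160,
        agglomerateLevel = 100, kappa = 0.08,
        noiseSd = 5, seed = 1L, maxAttempts = 200000L) {
    lighting <- match.arg(lighting)
    new("SceneParams", width = as.integer(width), height = as.integer(height),
        targetCoverage = targetCoverage,
        agglomerateFraction = agglomerateFraction,
        radiusMedian = radiusMedian, radiusShape = radiusShape,
        clusterMeanSize = clusterMeanSize, clusterRadius = clusterRadius,
        lighting = lighting,
        backgroundLevel = backgroundLevel, particleLevel = particleLevel,
        agglomerateLevel = agglomerateLevel, kappa = kappa,
        noiseSd = noiseSd, seed = as.integer(seed),
        maxAttempts = as.integer(maxAttempts))
}

# Linear indices of the pixels of a disk at (cx, cy) radius r, rasterised
# over pixel centers (j - 0.5, i - 0.5), clipped to the H x W frame.
.diskIndices <- function(cx, cy, r, W, H) {
    j0 <- max(1L, as.integer(floor(cx - r + 0.5)))
    j1 <- min(W, as.integer(ceiling(cx + r + 0.5)))
    i0 <- max(1L, as.integer(floor(cy - r + 0.5)))
    i1 <- min(H, as.integer(ceiling(cy + r + 0.5)))
    if (j0 > j1 || i0 > i1) return(integer(0))
    ii <- i0:i1; jj <- j0:j1
    dy2 <- ((ii - 0.5) - cy)^2
    dx2 <- ((jj - 0.5) - cx)^2
    w <- which(outer(dy2, dx2, "+") <= r^2)
    if (!length(w)) return(integer(0))
    ri <- ((w - 1L) %% length(ii)) + i0
    ci <- ((w - 1L) %/% length(ii)) + j0
    (ci - 1L) * H + ri
}

#' Generate one synthetic flow-pattern scene
#'
#' Places dispersed particles as a homogeneous point process of lognormal
#' disks and agglomerates as parent-offspring (Thomas-type) clusters
#' (parents uniform, offspring displaced by an isotropic Gaussian), adding
#' material until the target agglomerate area and then the target total
#' coverage are reached. Rendering: background at `backgroundLevel`;
#' dispersed powder, a flowing monolayer, at `particleLevel` regardless of
#' in-plane disk overlap; agglomerate pixels, stacked cohesive material, at
#' `agglomerateLevel * exp(-kappa * (m - 1))` where m is the number of
#' cluster-member disks covering the pixel. Gaussian noise is added and
#' intensities are clipped to [0, 255]; frontlighting inverts the image.
#' Ground-truth labels record cluster membership, not darkness, so the
#' truth is independent of the rendering used to detect it. Identical
#' parameters (including the seed) give byte-identical scenes.
#'
#' @param params a [SceneParams-class].
#' @return A [SyntheticScene-class].
#' @examples
#' sc <- generateScene(sceneParams(width = 128, height = 128,
#'     targetCoverage = 0.2, agglomerateFraction = 0.4, noiseSd = 0,
#'     seed = 42))
#' sceneTruth(sc)
#' @export
generateScene <- function(params) {
    stopifnot(is(params, "SceneParams"))
    withr::with_seed(params@seed, .renderScene(params),
        .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
        .rng_sample_kind = "Rejection")
}

.renderScene <- function(p) {
    W <- p@width; H <- p@height; A <- as.numeric(W) * H
    label <- matrix(0L, H, W)
    stack <- matrix(0L, H, W)        # cluster-member disks per pixel
    targetCovered <- round(p@targetCoverage * A)
    targetAg <- round(p@agglomerateFraction * targetCovered)
    covered <- 0; agPix <- 0
    attempts <- 0L
    drawRadius <- function() max(2, stats::rlnorm(1,
        meanlog = log(p@radiusMedian), sdlog = p@radiusShape))

    while (agPix < targetAg) {
        attempts <- attempts + 1L
        if (attempts > p@maxAttempts)
            stop("unreachable target coverage: placement attempts exhausted")
        px <- stats::runif(1, 0, W); py <- stats::runif(1, 0, H)
        nOff <- 1L + stats::rpois(1, max(p@clusterMeanSize - 1, 0))
        for (k in seq_len(nOff)) {
            cx <- px + stats::rnorm(1, 0, p@clusterRadius)
            cy <- py + stats::rnorm(1, 0, p@clusterRadius)
            idx <- .diskIndices(cx, cy, drawRadius(), W, H)
            if (length(idx)) {
                lab <- label[idx]
                covered <- covered + sum(lab == 0L)
                agPix <- agPix + sum(lab != 2L)
                label[idx] <- 2L
                stack[idx] <- stack[idx] + 1L
            }
            if (agPix >= targetAg) break
        }
    }
    while (covered < targetCovered) {
        attempts <- attempts + 1L
        if (attempts > p@maxAttempts)
            stop("unreachable target coverage: placement attempts exhausted")
        cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
        idx <- .diskIndices(cx, cy, drawRadius(), W, H)
        if (length(idx)) {
            fresh <- idx[label[idx] == 0L]
            covered <- covered + length(fresh)
            label[fresh] <- 1L
        }
    }

    img <- matrix(p@backgroundLevel, H, W)
    img[label == 1L] <- p@particleLevel
    agSel <- label == 2L
    if (any(agSel))
        img[agSel] <- p@agglomerateLevel * exp(-p@kappa * (stack[agSel] - 1L))
    if (p@noiseSd > 0)
        img <- img + stats::rnorm(A, 0, p@noiseSd)
    img <- round(pmin(pmax(img, 0), 255))
    if (p@lighting == "frontlight") img <- 255 - img

    truthFi <- 100 * covered / A
    truthAg <- if (covered > 0) agPix / covered else 0
    new("SyntheticScene", image = GrayImage(img, 8L), labels = label,
        truthFi = truthFi, truthAg = truthAg, params = p)
}

#' Write a suite of synthetic fixtures to disk
#'
#' Generates one scene per grid point (coverage x agglomerate fraction x
#' noise x seed), writing an 8-bit TIFF, a JSON ground-truth sidecar
#' (truth_fi, truth_ag, seed, parameters) and a manifest CSV listing every
#' fixture with its seed, so the suite can be regenerated identically.
#'
#' @param dir output directory (created if missing).
#' @param coverages target coverages, fractions in (0, 1).
#' @param agFractions agglomerate fractions in [0, 1].
#' @param noiseSds noise levels in gray levels.
#' @param seeds integer seeds; every grid point is generated at every seed.
#' @param ... further arguments to [sceneParams()] (frame size, lighting,
#'   intensity model).
#' @return invisibly, the manifest data.frame; its path is
#'   `file.path(dir, "manifest.csv")`.
#' @export
makeFixtureSuite <- function(dir, coverages, agFractions, noiseSds = 0,
        seeds = 1L, ...) {
    grid <- expand.grid(coverage = coverages, agFraction = agFractions,
        noiseSd = noiseSds, seed = as.integer(seeds))
    if (nrow(grid) == 0L) stop("empty fixture grid")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        g <- grid[i, ]
        params <- sceneParams(targetCoverage = g$coverage,
            agglomerateFraction = g$agFraction, noiseSd = g$noiseSd,
            seed = g$seed, ...)
        scene <- generateScene(params)
        stem <- sprintf("scene_c%03.0f_a%03.0f_n%02.0f_s%d",
            1000 * g$coverage, 100 * g$agFraction, g$noiseSd, g$seed)
        imgPath <- file.path(dir, paste0(stem, ".tif"))
        sidePath <- file.path(dir, paste0(stem, ".json"))
        writeFlowImage(scene@image, imgPath)
        jsonlite::write_json(list(truth_fi = scene@truthFi,
            truth_ag = scene@truthAg, seed = g$seed,
            params = list(width = params@width, height = params@height,
                target_coverage = g$coverage,
                agglomerate_fraction = g$agFraction,
                noise_sd = g$noiseSd, lighting = params@lighting)),
            sidePath, auto_unbox = TRUE, digits = NA)
        rows[[i]] <- data.frame(file = basename(imgPath),
            sidecar = basename(sidePath),
            coverage = g$coverage, ag_fraction = g$agFraction,
            noise_sd = g$noiseSd, seed = g$seed,
            truth_fi = scene@truthFi, truth_ag = scene@truthAg,
            stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
        row.names = FALSE)
    invisible(manifest)
}
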