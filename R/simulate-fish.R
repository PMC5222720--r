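## Voxel-centre coordinates in micrometres along one axis
axisCoords <- function(n, vs) (seq_len(n) - 0.5) * vs

## Uniform draw inside a sphere of radius r about `center` (um), by rejection
runifBall <- function(center, r, maxAttempts = 1000L) {
    for (i in seq_len(maxAttempts)) {
        p <- runif(3L, -r, r)
        if (sum(p^2) <= r^2) return(center + p)
    }
    stop("failed to place a point inside the nucleus after ",
         maxAttempts, " attempts")
}

## Random 3D unit vector
runifDirection <- function() {
    repeat {
        v <- rnorm(3L)
        n <- sqrt(sum(v^2))
        if (n > 1e-12) return(v / n)
    }
}

#' Simulate a two-channel 3D RNA-FISH nucleus image
#'
#' Each channel holds \code{nClouds} fluorescence clouds; a cloud is the sum
#' of \code{nPuncta} isotropic Gaussian puncta (sigma \code{punctumSigma})
#' whose centres are normal about the cloud centre with standard deviation
#' \code{cloudSpread} - the generative dispersion. Cloud centres are drawn
#' uniformly inside the nucleus sphere (rejection-sampled, with an error
#' after bounded attempts) and same-channel centres keep a minimum
#' separation. Channel-2 clouds are paired to channel-1 clouds and displaced
#' by \code{interChannelOffset} along a random direction, so inter-channel
#' overlap runs from complete (offset 0) to none (offset much larger than
#' the cloud extent). Gaussian background noise is added and the image is
#' clipped at zero. Identical seeds give identical voxel arrays.
#'
#' @param config a [FishSimConfig-class].
#' @return a [NucleusImage-class] with ground truth (cloud centres in um,
#'   spreads, offset, cloud counts).
#' @export
simulateNucleus <- function(config) {
    stopifnot(is(config, "FishSimConfig"))
    validObject(config)
    set.seed(config@seed)
    dims <- config@shape
    vs <- config@voxelSize
    center <- dims * vs / 2

    placeCenters <- function(n, maxAttempts = 1000L) {
        centers <- matrix(NA_real_, n, 3L)
        for (i in seq_len(n)) {
            ok <- FALSE
            for (a in seq_len(maxAttempts)) {
                p <- runifBall(center, config@nucleusRadius)
                if (i == 1L || all(sqrt(colSums((t(centers[seq_len(i - 1L), ,
                        drop = FALSE]) - p)^2)) >= config@cloudMinSeparation)) {
                    centers[i, ] <- p; ok <- TRUE; break
                }
            }
            if (!ok) stop("could not separate ", n,
                          " cloud centres inside the nucleus")
        }
        centers
    }

    c1 <- placeCenters(config@nClouds[1L])
    c2 <- matrix(NA_real_, config@nClouds[2L], 3L)
    for (j in seq_len(config@nClouds[2L])) {
        if (j <= nrow(c1)) {
            if (config@interChannelOffset == 0) {
                c2[j, ] <- c1[j, ]
            } else {
                placed <- FALSE
                for (a in seq_len(1000L)) {
                    p <- c1[j, ] + config@interChannelOffset * runifDirection()
                    if (sum((p - center)^2) <= config@nucleusRadius^2 ||
                        a == 1000L) { c2[j, ] <- p; placed <- TRUE; break }
                }
                if (!placed) c2[j, ] <- c1[j, ] +
                        config@interChannelOffset * runifDirection()
            }
        } else {
            c2[j, ] <- runifBall(center, config@nucleusRadius)
        }
    }

    zc <- axisCoords(dims[1L], vs[1L])
    yc <- axisCoords(dims[2L], vs[2L])
    xc <- axisCoords(dims[3L], vs[3L])

    renderChannel <- function(centers, spread, peak) {
        img <- array(0, dim = dims)
        if (nrow(centers) == 0L) return(img)
        sig <- config@punctumSigma
        half <- 4 * sig
        for (i in seq_len(nrow(centers))) {
            pts <- matrix(rnorm(3L * config@nPuncta, sd = spread),
                          ncol = 3L, byrow = TRUE)
            pts <- sweep(pts, 2L, centers[i, ], `+`)
            for (k in seq_len(config@nPuncta)) {
                p <- pts[k, ]
                zi <- which(abs(zc - p[1L]) <= half)
                yi <- which(abs(yc - p[2L]) <= half)
                xi <- which(abs(xc - p[3L]) <= half)
                if (!length(zi) || !length(yi) || !length(xi)) next
                gz <- exp(-(zc[zi] - p[1L])^2 / (2 * sig^2))
                gy <- exp(-(yc[yi] - p[2L])^2 / (2 * sig^2))
                gx <- exp(-(xc[xi] - p[3L])^2 / (2 * sig^2))
                img[zi, yi, xi] <- img[zi, yi, xi, drop = FALSE] +
                    peak * (gz %o% gy %o% gx)
            }
        }
        img
    }

    ch1 <- renderChannel(c1, config@cloudSpread[1L], config@peakIntensity[1L])
    ch2 <- renderChannel(c2, config@cloudSpread[2L], config@peakIntensity[2L])
    nvox <- prod(dims)
    ch1 <- pmax(ch1 + array(rnorm(nvox, config@backgroundMean,
                                  config@backgroundSd), dims), 0)
    ch2 <- pmax(ch2 + array(rnorm(nvox, config@backgroundMean,
                                  config@backgroundSd), dims), 0)

    NucleusImage(list(ch1, ch2), vs, groundTruth = list(
        centers = list(ch1 = c1, ch2 = c2),
        cloudSpread = config@cloudSpread,
        interChannelOffset = config@interChannelOffset,
        nClouds = config@nClouds,
        nPuncta = config@nPuncta,
        backgroundMean = config@backgroundMean))
}

#' Simulate a labelled population of nuclei
#'
#' For each group, draws \code{nNuclei} nuclei; each nucleus is independently
#' "positive" (carries the configured clouds) with the group's probability,
#' and pure background otherwise. Ground-truth positivity labels are kept,
#' emulating per-embryo cell populations scored for the presence of a
#' lncRNA cloud.
#'
#' @param config a [FishSimConfig-class] template (its seed fixes all draws).
#' @param nNuclei nuclei per group.
#' @param positiveFractionByGroup named numeric of positive probabilities.
#' @return list: \code{nuclei} (list of [NucleusImage-class]), \code{labels}
#'   (data.frame: nucleus_id, group, true_positive).
#' @export
simulatePopulation <- function(config, nNuclei, positiveFractionByGroup) {
    if (any(positiveFractionByGroup < 0 | positiveFractionByGroup > 1))
        stop("positive fractions must lie in [0,1]")
    set.seed(config@seed)
    groups <- names(positiveFractionByGroup)
    if (is.null(groups)) stop("'positiveFractionByGroup' must be named")
    labels <- data.frame(
        nucleus_id = sprintf("%s_n%03d", rep(groups, each = nNuclei),
                             rep(seq_len(nNuclei), length(groups))),
        group = rep(groups, each = nNuclei), stringsAsFactors = FALSE)
    labels$true_positive <- runif(nrow(labels)) <
        positiveFractionByGroup[labels$group]
    seeds <- sample.int(.Machine$integer.max - 1L, nrow(labels))
    nuclei <- lapply(seq_len(nrow(labels)), function(i) {
        cfg <- config
        cfg@seed <- seeds[i]
        if (!labels$true_positive[i]) cfg@nClouds <- c(0L, 0L)
        simulateNucleus(cfg)
    })
    names(nuclei) <- labels$nucleus_id
    list(nuclei = nuclei, labels = labels)
}
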