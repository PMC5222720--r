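#' Computed intensity threshold (Otsu) for one channel
#'
#' Builds a 256-bin histogram between the channel's minimum and maximum
#' intensity and returns the bin edge that maximizes the between-class
#' variance of the two classes it induces (values below the edge versus
#' values at or above it) - Otsu's method on the per-nucleus intensity
#' distribution. Deterministic; ties resolve to the smallest edge.
#'
#' @param image numeric array (any shape) with at least two distinct values.
#' @param levels number of histogram bins.
#' @return the threshold intensity.
#' @export
computeThreshold <- function(image, levels = 256L) {
    v <- as.numeric(image)
    lo <- min(v); hi <- max(v)
    if (lo == hi) stop("no threshold separable: image is constant")
    edges <- seq(lo, hi, length.out = levels + 1L)
    bin <- findInterval(v, edges, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nbins = levels)
    sums <- numeric(levels)
    rs <- rowsum(v, bin)
    sums[as.integer(rownames(rs))] <- rs
    cumN <- cumsum(cnt); cumS <- cumsum(sums)
    n <- length(v); total <- cumS[levels]
    ks <- seq_len(levels - 1L)
    n0 <- cumN[ks]; n1 <- n - n0
    valid <- n0 > 0L & n1 > 0L
    mu0 <- cumS[ks] / n0
    mu1 <- (total - cumS[ks]) / n1
    bcv <- ifelse(valid, (n0 / n) * (n1 / n) * (mu0 - mu1)^2, -Inf)
    edges[which.max(bcv) + 1L]
}

#' Dispersion of a fluorescence signal
#'
#' A unitless compactness measure: the intensity-weighted mean Euclidean
#' distance (in micrometres) of the mask's voxels from the intensity-weighted
#' centroid, divided by the radius of the sphere whose volume equals the mask
#' volume. A single voxel scores 0; a uniform solid ball scores 3/4 in the
#' continuum limit; scattered signals score higher. Invariant under voxel-grid
#' translation and (up to discretization) under isotropic rescaling.
#'
#' @param image numeric 3D array supplying intensity weights.
#' @param mask integer vector of linear voxel indices (nonempty).
#' @param voxelSize micrometres per voxel, (z, y, x).
#' @return the dispersion value (>= 0).
#' @export
cloudDispersion <- function(image, mask, voxelSize) {
    if (!length(mask)) stop("mask is empty")
    dims <- dim(image)
    w <- as.numeric(image[mask])
    if (sum(w) <= 0) w <- rep(1, length(mask))
    xyz <- (arrayInd(mask, dims) - 0.5) %*% diag(voxelSize)
    centroid <- colSums(xyz * w) / sum(w)
    d <- sqrt(rowSums(sweep(xyz, 2L, centroid)^2))
    meanDist <- sum(w * d) / sum(w)
    vol <- length(mask) * prod(voxelSize)
    rEq <- (3 * vol / (4 * pi))^(1 / 3)
    meanDist / rEq
}

#' Segment fluorescence clouds in one channel
#'
#' Thresholds the channel (inclusive, >=), labels 26-connected components of
#' the above-threshold voxel set, discards components smaller than
#' \code{minVoxels}, and measures each surviving cloud: voxel count, volume
#' (voxel count times voxel volume, in cubic micrometres), intensity-weighted
#' centroid (micrometres), integrated intensity, and dispersion. Clouds are
#' ordered by integrated intensity, descending. An empty result is allowed.
#'
#' @param image numeric 3D array (z, y, x).
#' @param threshold intensity threshold (e.g. from [computeThreshold()]).
#' @param voxelSize micrometres per voxel, (z, y, x).
#' @param minVoxels smallest component kept (default 27, about a 3x3x3 speck).
#' @return data.frame (cloud_id, n_voxels, volume_um3, sum_intensity,
#'   centroid_z, centroid_y, centroid_x, dispersion) with the voxel masks
#'   (linear indices) in \code{attr(, "masks")}.
#' @export
segmentClouds <- function(image, threshold, voxelSize, minVoxels = 27L) {
    dims <- dim(image)
    fg <- which(image >= threshold)
    emptyOut <- data.frame(cloud_id = integer(), n_voxels = integer(),
                           volume_um3 = numeric(), sum_intensity = numeric(),
                           centroid_z = numeric(), centroid_y = numeric(),
                           centroid_x = numeric(), dispersion = numeric())
    attr(emptyOut, "masks") <- list()
    if (!length(fg)) return(emptyOut)

    mark <- integer(prod(dims))
    mark[fg] <- seq_along(fg)
    coords <- arrayInd(fg, dims)
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[offs[, 1L] > 0 | (offs[, 1L] == 0 & offs[, 2L] > 0) |
                 (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0), ,
                 drop = FALSE]
    ei <- integer(0); ej <- integer(0)
    for (k in seq_len(nrow(offs))) {
        nb <- sweep(coords, 2L, offs[k, ], `+`)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
              nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
        if (!any(ok)) next
        lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * dims[1L] +
               (nb[ok, 3L] - 1L) * dims[1L] * dims[2L]
        j <- mark[lin]
        hit <- j > 0L
        ei <- c(ei, which(ok)[hit]); ej <- c(ej, j[hit])
    }
    g <- igraph::make_graph(rbind(ei, ej), n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
    keep <- as.integer(names(which(table(memb) >= minVoxels)))
    if (!length(keep)) return(emptyOut)

    rows <- lapply(keep, function(cid) {
        mask <- fg[memb == cid]
        w <- as.numeric(image[mask])
        xyz <- (arrayInd(mask, dims) - 0.5) %*% diag(voxelSize)
        ctr <- colSums(xyz * w) / sum(w)
        data.frame(n_voxels = length(mask),
                   volume_um3 = length(mask) * prod(voxelSize),
                   sum_intensity = sum(w),
                   centroid_z = ctr[1L], centroid_y = ctr[2L],
                   centroid_x = ctr[3L],
                   dispersion = cloudDispersion(image, mask, voxelSize))
    })
    out <- do.call(rbind, rows)
    masks <- lapply(keep, function(cid) fg[memb == cid])
    ord <- order(-out$sum_intensity)
    out <- out[ord, , drop = FALSE]
    masks <- masks[ord]
    out <- cbind(cloud_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    attr(out, "masks") <- masks
    out
}

#' Per-nucleus dispersion of the whole above-threshold signal
#'
#' One dispersion value per channel and nucleus, computed with
#' [cloudDispersion()] over the union of all segmented clouds' voxels. A
#' signal that scatters into several fragments therefore scores high (the
#' fragments sit far from the common centroid), whereas per-cloud dispersion
#' would score each compact fragment low. \code{NA} when no cloud survives
#' segmentation.
#'
#' @param image numeric 3D array.
#' @param threshold intensity threshold.
#' @param voxelSize micrometres per voxel, (z, y, x).
#' @param minVoxels smallest component kept.
#' @return a single dispersion value, or NA.
#' @export
signalDispersion <- function(image, threshold, voxelSize, minVoxels = 27L) {
    cl <- segmentClouds(image, threshold, voxelSize, minVoxels = minVoxels)
    masks <- attr(cl, "masks")
    if (!length(masks)) return(NA_real_)
    cloudDispersion(image, sort(unique(unlist(masks))), voxelSize)
}

#' Per-nucleus co-localization of the two channels
#'
#' Takes the union of the above-threshold voxel sets of the two channels and
#' computes the Spearman correlation (average ranks) of the paired
#' intensities over that set - positive when the two signals occupy the same
#' territory, negative when each channel is bright where the other is
#' background. Fewer than \code{minVoxels} usable voxels, or zero variance in
#' either channel over the set, leaves the score undefined (flagged, not 0).
#'
#' @param ch1,ch2 same-shape numeric arrays.
#' @param thr1,thr2 per-channel intensity thresholds.
#' @param minVoxels minimum voxels for a defined score.
#' @return list: \code{threshold_ch1}, \code{threshold_ch2},
#'   \code{n_voxels_used}, \code{spearman_r} (NA when undefined),
#'   \code{defined}.
#' @export
colocalize <- function(ch1, ch2, thr1, thr2, minVoxels = 3L) {
    stopifnot(identical(dim(ch1), dim(ch2)))
    u <- which(ch1 >= thr1 | ch2 >= thr2)
    a <- as.numeric(ch1[u]); b <- as.numeric(ch2[u])
    defined <- length(u) >= minVoxels && sd(a) > 0 && sd(b) > 0
    r <- if (defined) cor(a, b, method = "spearman") else NA_real_
    list(threshold_ch1 = thr1, threshold_ch2 = thr2,
         n_voxels_used = length(u), spearman_r = r, defined = defined)
}

#' Co-localization scores over a population of nuclei
#'
#' Applies [colocalize()] to every nucleus, with per-nucleus computed (Otsu)
#' thresholds unless explicit ones are given, and reports the per-nucleus
#' Spearman scores with their median - the population statistic used to
#' summarize whether the two lncRNA signals co-localize.
#'
#' @param nuclei list of [NucleusImage-class].
#' @param thresholds optional numeric length-2 vector of fixed thresholds.
#' @return list: \code{perNucleus} data.frame (nucleus_id, threshold_ch1,
#'   threshold_ch2, n_voxels, spearman_r), \code{median_r} over defined
#'   scores.
#' @export
colocalizeNuclei <- function(nuclei, thresholds = NULL) {
    ids <- names(nuclei)
    if (is.null(ids)) ids <- sprintf("n%03d", seq_along(nuclei))
    rows <- lapply(seq_along(nuclei), function(i) {
        img <- nuclei[[i]]
        t1 <- if (is.null(thresholds)) computeThreshold(channelArray(img, 1L))
              else thresholds[1L]
        t2 <- if (is.null(thresholds)) computeThreshold(channelArray(img, 2L))
              else thresholds[2L]
        cl <- colocalize(channelArray(img, 1L), channelArray(img, 2L), t1, t2)
        data.frame(nucleus_id = ids[i], threshold_ch1 = t1, threshold_ch2 = t2,
                   n_voxels = cl$n_voxels_used, spearman_r = cl$spearman_r)
    })
    per <- do.call(rbind, rows)
    list(perNucleus = per, median_r = median(per$spearman_r, na.rm = TRUE))
}

#' Count clouds per nucleus and tabulate patterns by group
#'
#' For every nucleus and channel, computes (or takes) the intensity
#' threshold, segments clouds, and records the cloud count clipped to the
#' categories \code{"0"}, \code{"1"}, \code{"2+"}. When the above-threshold
#' set covers more than \code{maxForegroundFraction} of the image the channel
#' is treated as signal-free (a threshold inside pure background noise splits
#' the noise itself, not signal from background). Per group, returns category
#' counts per channel and the positive fraction (at least one cloud).
#'
#' @param nuclei list of [NucleusImage-class].
#' @param groups group label per nucleus.
#' @param thresholds optional fixed length-2 thresholds (else per-nucleus
#'   Otsu).
#' @param voxelGuard maximum above-threshold voxel fraction before a channel
#'   is declared signal-free.
#' @param minVoxels smallest cloud kept.
#' @return list: \code{perNucleus} data.frame (nucleus_id, group, channel,
#'   n_clouds, category), \code{counts} list of groups x category matrices
#'   (one per channel), \code{positiveFraction} groups x channels matrix.
#' @export
countCloudPatterns <- function(nuclei, groups, thresholds = NULL,
                               voxelGuard = 0.25, minVoxels = 27L) {
    stopifnot(length(groups) == length(nuclei))
    ids <- names(nuclei)
    if (is.null(ids)) ids <- sprintf("n%03d", seq_along(nuclei))
    cats <- c("0", "1", "2+")
    rows <- lapply(seq_along(nuclei), function(i) {
        img <- nuclei[[i]]
        do.call(rbind, lapply(1:2, function(ch) {
            arr <- channelArray(img, ch)
            thr <- if (is.null(thresholds)) computeThreshold(arr)
                   else thresholds[ch]
            nc <- if (mean(arr >= thr) > voxelGuard) 0L
                  else nrow(segmentClouds(arr, thr, voxelSize(img),
                                          minVoxels = minVoxels))
            data.frame(nucleus_id = ids[i], group = groups[i], channel = ch,
                       n_clouds = nc,
                       category = if (nc >= 2L) "2+" else as.character(nc))
        }))
    })
    per <- do.call(rbind, rows)
    glv <- unique(groups)
    counts <- lapply(1:2, function(ch) {
        m <- t(vapply(glv, function(g) {
            sub <- per[per$group == g & per$channel == ch, ]
            vapply(cats, function(cc) sum(sub$category == cc), 0L)
        }, stats::setNames(integer(3), cats)))
        rownames(m) <- glv
        m
    })
    posFrac <- matrix(NA_real_, length(glv), 2L,
                      dimnames = list(glv, c("ch1", "ch2")))
    for (ch in 1:2) for (g in glv) {
        sub <- per[per$group == g & per$channel == ch, ]
        posFrac[g, ch] <- mean(sub$n_clouds >= 1L)
    }
    list(perNucleus = per, counts = counts, positiveFraction = posFrac)
}

#' Trend of positive fractions across ordered groups
#'
#' Spearman correlation (average ranks) of per-group positive fractions
#' against the group rank in \code{groupOrder} - the statistic relating the
#' proportion of signal-positive cells to developmental stage. Constant
#' fractions leave the correlation undefined (flagged).
#'
#' @param fractions named numeric of per-group fractions.
#' @param groupOrder ordered group labels (>= 3).
#' @return list: \code{r}, \code{defined}, \code{n_groups}.
#' @export
fractionTrend <- function(fractions, groupOrder) {
    if (length(groupOrder) < 3L) stop("at least 3 groups are required")
    if (!all(groupOrder %in% names(fractions)))
        stop("every group in 'groupOrder' needs a fraction")
    f <- fractions[groupOrder]
    if (length(unique(f)) == 1L)
        return(list(r = NA_real_, defined = FALSE,
                    n_groups = length(groupOrder)))
    list(r = cor(f, seq_along(groupOrder), method = "spearman"),
         defined = TRUE, n_groups = length(groupOrder))
}
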