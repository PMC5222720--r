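test_that("the computed threshold equals brute-force variance maximization", {
    ## half voxels at 10, half at 200: threshold strictly between the modes
    v <- c(rep(10, 500), rep(200, 500))
    thr <- computeThreshold(v)
    expect_gt(thr, 10); expect_lt(thr, 200)
    expect_equal(thr, bruteForceOtsu(v))

    ## a single voxel at the high value
    v2 <- c(rep(10, 999), 200)
    expect_equal(computeThreshold(v2), bruteForceOtsu(v2))

    ## random histograms from assorted generators
    set.seed(71)
    for (i in 1:50) {
        v <- switch(1L + i %% 4,
            rnorm(400, 50, 10),
            c(rnorm(300, 20, 5), rnorm(100, 90, 8)),
            rexp(400, 1 / 30),
            sample(0:255, 400, TRUE))
        expect_equal(computeThreshold(v), bruteForceOtsu(v))
    }
    expect_error(computeThreshold(rep(3, 10)), "no threshold separable")
})

test_that("cloud segmentation finds 26-connected components", {
    dims <- c(10L, 20L, 20L)
    vs <- c(0.1, 0.1, 0.1)
    a <- array(0, dims)
    a[2:4, 2:4, 2:4] <- 10                 # blob 1: 27 voxels
    a[7:9, 14:17, 14:17] <- 20             # blob 2: 48 voxels
    cl <- segmentClouds(a, 5, vs, minVoxels = 10L)
    expect_identical(nrow(cl), 2L)
    expect_identical(cl$cloud_id, 1:2)     # brighter integrated first
    expect_identical(cl$n_voxels, c(48L, 27L))

    ## diagonal touch merges under 26-connectivity
    b <- array(0, dims)
    b[2, 2, 2] <- 1; b[3, 3, 3] <- 1
    expect_identical(nrow(segmentClouds(b, 0.5, vs, minVoxels = 1L)), 1L)

    ## nothing above threshold
    expect_identical(nrow(segmentClouds(a, 100, vs)), 0L)

    ## volume arithmetic: 100 voxels at (0.1 um)^3 -> 0.1 um^3
    d <- array(0, c(5L, 10L, 10L))
    d[1, 1:10, 1:10] <- 7
    cld <- segmentClouds(d, 7, vs, minVoxels = 1L)
    expect_equal(cld$volume_um3, 0.1)

    ## volume conservation at minVoxels = 1
    set.seed(5)
    e <- array(runif(prod(dims)), dims)
    cle <- segmentClouds(e, 0.8, vs, minVoxels = 1L)
    expect_equal(sum(cle$n_voxels), sum(e >= 0.8))
    expect_equal(sum(cle$volume_um3), sum(e >= 0.8) * prod(vs))
})

test_that("dispersion is calibrated, translation- and scale-invariant", {
    vs <- c(1, 1, 1)
    dims <- c(45L, 45L, 45L)
    arr <- array(1, dims)
    idx <- seq_len(prod(dims))
    co <- arrayInd(idx, dims) - 0.5

    ## single voxel -> 0
    expect_equal(cloudDispersion(arr, idx[1L], vs), 0)

    ## uniform digital ball of radius 20: continuum value 3/4
    ctr <- c(22.5, 22.5, 22.5)
    ball <- idx[rowSums(sweep(co, 2, ctr)^2) <= 20^2]
    D <- cloudDispersion(arr, ball, vs)
    expect_lt(abs(D - 0.75), 0.02)

    ## two single-voxel fragments at distance d: D = (d/2) / rEq
    dims2 <- c(3L, 3L, 15L)
    arr2 <- array(0, dims2)
    m1 <- 2L + (2L - 1L) * 3L + (2L - 1L) * 9L          # (2,2,2)
    m2 <- 2L + (2L - 1L) * 3L + (12L - 1L) * 9L         # (2,2,12)
    arr2[c(m1, m2)] <- 1
    dHand <- 10                                          # along x, um
    rEq <- (3 * 2 / (4 * pi))^(1 / 3)
    expect_equal(cloudDispersion(arr2, c(m1, m2), vs), (dHand / 2) / rEq)

    ## exact under voxel-grid translation
    dims3 <- c(20L, 20L, 20L)
    base <- array(0, dims3)
    set.seed(8)
    sub <- array(runif(27) + 0.5, c(3L, 3L, 3L))
    a1 <- base; a1[2:4, 2:4, 2:4] <- sub
    a2 <- base; a2[10:12, 9:11, 14:16] <- sub
    m1s <- which(a1 > 0); m2s <- which(a2 > 0)
    expect_equal(cloudDispersion(a1, m1s, vs), cloudDispersion(a2, m2s, vs),
                 tolerance = 1e-12)

    ## isotropic rescaling of voxel size changes D by < 3%
    Dsmall <- cloudDispersion(a1, m1s, c(0.1, 0.1, 0.1))
    Dbig <- cloudDispersion(a1, m1s, c(0.4, 0.4, 0.4))
    expect_lt(abs(Dsmall - Dbig) / Dsmall, 0.03)

    expect_error(cloudDispersion(arr, integer(0), vs), "empty")
})

test_that("whole-signal dispersion rises when a signal fragments", {
    dims <- c(12L, 30L, 30L); vs <- c(0.2, 0.1, 0.1)
    one <- array(0, dims); one[5:8, 13:18, 13:18] <- 10
    two <- array(0, dims)
    two[5:8, 3:6, 3:6] <- 10; two[5:8, 24:27, 24:27] <- 10
    dOne <- signalDispersion(one, 5, vs, minVoxels = 10L)
    dTwo <- signalDispersion(two, 5, vs, minVoxels = 10L)
    expect_gt(dTwo, dOne * 2)
    expect_true(is.na(signalDispersion(array(0, dims), 5, vs)))
})

test_that("co-localization responds to monotone relations and thresholds", {
    dims <- c(6L, 10L, 10L)
    set.seed(4)
    ch1 <- array(runif(prod(dims), 0, 100), dims)
    ch2 <- 2 * ch1
    expect_equal(colocalize(ch1, ch2, 50, 100)$spearman_r, 1)
    ch3 <- max(ch1) - ch1
    expect_equal(colocalize(ch1, ch3, 50, 50)$spearman_r, -1)

    ## fewer than 3 usable voxels -> undefined, flagged
    lo <- array(0, dims); lo[1, 1, 1] <- 10
    out <- colocalize(lo, lo, 5, 5)
    expect_false(out$defined)
    expect_true(is.na(out$spearman_r))
})

test_that("pattern counting clips at two clouds and splits by group", {
    cfgTwo <- FishSimConfig(shape = c(20L, 56L, 56L),
                            voxelSize = c(0.25, 0.1, 0.1),
                            nucleusRadius = 2.2, nClouds = c(2L, 2L),
                            cloudSpread = 0.35, cloudMinSeparation = 2.6,
                            seed = 14L)
    nucTwo <- lapply(1:3, function(s) {
        c2 <- cfgTwo; c2@seed <- 100L + s; simulateNucleus(c2)
    })
    cfgZero <- smallFishConfig(seed = 15L, nClouds = c(0L, 0L))
    nucZero <- list(simulateNucleus(cfgZero))
    pat <- countCloudPatterns(c(nucTwo, nucZero),
                              c(rep("two", 3L), "none"))
    subTwo <- pat$perNucleus[pat$perNucleus$group == "two" &
                             pat$perNucleus$channel == 1L, ]
    expect_true(all(subTwo$category == "2+"))
    expect_equal(unname(pat$positiveFraction["none", ]), c(0, 0))
    expect_equal(unname(pat$positiveFraction["two", "ch1"]), 1)
    expect_identical(unname(pat$counts[[1L]]["two", "2+"]), 3L)
})

test_that("fraction trends follow group order", {
    fr <- c(a = 0.9, b = 0.7, c = 0.5, d = 0.2, e = 0.1)
    expect_equal(fractionTrend(fr, names(fr))$r, -1)
    expect_equal(fractionTrend(fr, rev(names(fr)))$r, 1)

    set.seed(6)
    perm <- sample(fr)
    got <- fractionTrend(perm, names(fr))$r
    expect_equal(got, cor(perm[names(fr)], seq_along(fr),
                          method = "spearman"))

    flat <- fractionTrend(c(a = 0.5, b = 0.5, c = 0.5), c("a", "b", "c"))
    expect_false(flat$defined)
    expect_true(is.na(flat$r))
    expect_error(fractionTrend(fr[1:2], names(fr)[1:2]), "3 groups")
})

test_that("pattern comparisons use exact hypergeometric enumeration", {
    p <- comparePatterns(c(m = 5, b = 0), c(m = 0, b = 5))
    expect_equal(p$p_value, 2 / choose(10, 5))
    expect_equal(p$p_value,
                 enumFisher2x2(rbind(c(5, 0), c(0, 5))))

    ## proportional rows: odds ratio 1, p = 1
    expect_equal(comparePatterns(c(m = 4, b = 6), c(m = 2, b = 3))$p_value, 1)

    ## zero group margin
    expect_warning(pz <- comparePatterns(c(m = 0, b = 0), c(m = 3, b = 4)),
                   "zero margin")
    expect_equal(pz$p_value, 1)

    ## 3 categories, small total: exact; large total falls back to chi-square
    pe <- comparePatterns(c(a = 4, b = 3, c = 2), c(a = 1, b = 4, c = 5))
    expect_identical(pe$method, "fisher")
    expect_warning(
        pc <- comparePatterns(c(a = 40, b = 30, c = 20),
                              c(a = 10, b = 40, c = 50)),
        "chi-square")
    expect_identical(pc$method, "chisq")
    expect_error(comparePatterns(c(a = 1), c(b = 1)), "same pattern")
})

test_that("measurement comparison mirrors the score comparison contract", {
    expect_equal(compareMeasurements(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
    expect_equal(compareMeasurements(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
})
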