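## Small configurations reused across tests. Sizes are kept minimal; the
## study-scale conditions live in the constructors' defaults.

twoStageConfig <- function(seed = 1L, nCellsPost = 20L, rho = 0.7,
                           bfPre = 0.5, bfPost = 0.5, nPosX = 60L,
                           errorRate = 0, sexRatio = 1) {
    ScrnaSimConfig(
        nEmbryos = 2L,
        cellsPerEmbryo = c(pre = 10L, post = nCellsPost),
        stages = c("pre", "post"), zgaStage = "post",
        sexRatio = sexRatio, focalRho = rho,
        biallelicFractionByStage = c(pre = bfPre, post = bfPost),
        nPositionsPerChrom = c(X = nPosX, "7" = nPosX),
        nGenesPerChrom = c(X = 20L, "7" = 10L),
        lineageStages = "post",
        lineageProbs = c(TE = 0, EPI = 0, PE = 0),
        errorRate = errorRate, seed = seed)
}

## one cell-group per stage, all female, ZGA before the first stage
stageSeriesConfig <- function(seed, fractions, cellsPerStage = 40L,
                              nPosX = 60L, nPosAuto = 60L) {
    stages <- names(fractions)
    ScrnaSimConfig(
        nEmbryos = length(stages), cellsPerEmbryo = cellsPerStage,
        stages = stages, zgaStage = stages[1L], sexRatio = 1,
        biallelicFractionByStage = fractions,
        nPositionsPerChrom = c(X = nPosX, "7" = nPosAuto),
        nGenesPerChrom = c(X = 20L, "7" = 10L),
        lineageStages = stages[length(stages)],
        lineageProbs = c(TE = 0, EPI = 0, PE = 0),
        seed = seed)
}

smallFishConfig <- function(seed = 1L, ...) {
    FishSimConfig(shape = c(16L, 48L, 48L), voxelSize = c(0.25, 0.12, 0.12),
                  nucleusRadius = 2, seed = seed, ...)
}

randomAlleleTable <- function(seed, nRecords = 30L, nCells = 3L) {
    set.seed(seed)
    keys <- unique(data.frame(
        cell_id = sample(sprintf("c%d", seq_len(nCells)), nRecords, TRUE),
        chrom = sample(c("X", "7"), nRecords, TRUE),
        pos = sample.int(500L, nRecords, TRUE)))
    n <- nrow(keys)
    AlleleCountTable(data.frame(
        keys, gene = sample(sprintf("g%d", 1:5), n, TRUE),
        ref_count = rnbinom(n, mu = 6, size = 1.5),
        alt_count = rnbinom(n, mu = 3, size = 1.5)))
}

## record-by-record reference scan for callBiallelic
bruteForceBiallelic <- function(table, params) {
    r <- alleleRecords(table)
    out <- list()
    for (cell in unique(r$cell_id)) for (ch in unique(r$chrom)) {
        sub <- r[r$cell_id == cell & r$chrom == ch, , drop = FALSE]
        if (!nrow(sub)) next
        nCov <- 0L; nBi <- 0L; reads <- 0L
        for (i in seq_len(nrow(sub))) {
            tot <- sub$ref_count[i] + sub$alt_count[i]
            if (tot >= params@minTotalReads) {
                nCov <- nCov + 1L
                reads <- reads + tot
                if (min(sub$ref_count[i], sub$alt_count[i]) / tot >=
                    params@ratioThreshold)
                    nBi <- nBi + 1L
            }
        }
        out[[length(out) + 1L]] <- data.frame(
            cell_id = cell, chrom = ch, n_covered = nCov, n_biallelic = nBi,
            total_reads = reads,
            score = if (nCov >= params@minPositions) nBi / nCov else NA_real_,
            defined = nCov >= params@minPositions)
    }
    res <- do.call(rbind, out)
    res[order(res$cell_id, res$chrom), ]
}

## brute-force Otsu: scan every candidate edge, maximizing between-class
## variance computed directly from the voxel values
bruteForceOtsu <- function(v, levels = 256L) {
    v <- as.numeric(v)
    edges <- seq(min(v), max(v), length.out = levels + 1L)
    best <- -Inf; bestEdge <- NA_real_
    for (e in edges[2:levels]) {
        lo <- v[v < e]; hi <- v[v >= e]
        if (!length(lo) || !length(hi)) next
        w0 <- length(lo) / length(v); w1 <- 1 - w0
        bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
        if (bcv > best) { best <- bcv; bestEdge <- e }
    }
    bestEdge
}

## two-sided Fisher p for a 2x2 table by hypergeometric enumeration
enumFisher2x2 <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    pObs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
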