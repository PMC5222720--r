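oneCellTable <- function() {
    AlleleCountTable(data.frame(
        cell_id = "c1", chrom = "X", pos = c(100L, 200L, 300L), gene = "g1",
        ref_count = c(10L, 19L, 8L), alt_count = c(10L, 1L, 2L)))
}

test_that("bi-allelic calling applies both filters with inclusive boundary", {
    tab <- oneCellTable()      # ratios 0.5, 0.05, 0.2
    s <- biallelicScores(callBiallelic(tab, CallParams(0.2, 5L, 1L)))
    expect_identical(s$n_covered, 3L)
    expect_identical(s$n_biallelic, 2L)     # 0.20 is inclusive
    expect_equal(s$score, 2 / 3)

    s25 <- biallelicScores(callBiallelic(tab, CallParams(0.25, 5L, 1L)))
    expect_identical(s25$n_biallelic, 1L)

    ## under-covered (cell, chrom) entries are flagged, never silently 0
    sMin <- biallelicScores(callBiallelic(tab, CallParams(0.2, 5L, 5L)))
    expect_false(sMin$defined)
    expect_true(is.na(sMin$score))

    ## the read-depth normalization divides by total covered reads
    sr <- biallelicScores(callBiallelic(
        tab, CallParams(0.2, 5L, 1L, normalization = "reads")))
    expect_equal(sr$score, 2 / 50)

    empty <- callBiallelic(AlleleCountTable(alleleRecords(tab)[0, ]))
    expect_identical(nrow(biallelicScores(empty)), 0L)
})

test_that("calling matches a record-by-record brute-force scan", {
    params <- CallParams(0.2, 5L, 2L)
    for (s in 1:200) {
        tab <- randomAlleleTable(s)
        got <- biallelicScores(callBiallelic(tab, params))
        ref <- bruteForceBiallelic(tab, params)
        rownames(got) <- rownames(ref) <- NULL
        expect_equal(got[, colnames(ref)], ref)
    }
})

test_that("the threshold sweep is monotone with constant coverage", {
    thr <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
    for (s in 1:25) {
        sw <- thresholdSweep(randomAlleleTable(s, nRecords = 60L), thr,
                             CallParams(minTotalReads = 3L, minPositions = 1L))
        for (key in unique(paste(sw$cell_id, sw$chrom))) {
            sub <- sw[paste(sw$cell_id, sw$chrom) == key, ]
            sub <- sub[order(sub$threshold), ]
            expect_true(all(diff(sub$n_biallelic) <= 0))
            expect_identical(length(unique(sub$n_covered)), 1L)
        }
    }
    expect_error(thresholdSweep(randomAlleleTable(1), c(0.2, 0.6)), "0.5")

    ## threshold 0.5 counts exactly the perfectly balanced positions
    tab <- oneCellTable()
    s5 <- thresholdSweep(tab, 0.5, CallParams(minTotalReads = 5L,
                                              minPositions = 1L))
    expect_identical(s5$n_biallelic, 1L)
})

test_that("sequencing error inflates calls only at permissive thresholds", {
    mk <- function(err, seed) {
        cfg <- ScrnaSimConfig(
            nEmbryos = 1L, cellsPerEmbryo = 40L, stages = "s", zgaStage = "s",
            sexRatio = 1, biallelicFractionByStage = c(s = 0),
            autosomalBiallelicFraction = 0,
            nPositionsPerChrom = c(X = 100L), nGenesPerChrom = c(X = 10L),
            lineageStages = "s", lineageProbs = c(TE = 0, EPI = 0, PE = 0),
            coverageMean = 30, errorRate = err, seed = seed)
        simulateAlleleCounts(simulateExpression(cfg), cfg)
    }
    sweep0 <- thresholdSweep(mk(0, 17L), c(0.05, 0.3),
                             CallParams(minPositions = 1L))
    sweepE <- thresholdSweep(mk(0.05, 17L), c(0.05, 0.3),
                             CallParams(minPositions = 1L))
    callsAt <- function(sw, th) sum(sw$n_biallelic[sw$threshold == th])
    expect_gt(callsAt(sweepE, 0.05), callsAt(sweep0, 0.05) + 50)
    expect_lt(callsAt(sweepE, 0.3), callsAt(sweepE, 0.05) / 20)
})

test_that("rank-sum comparisons are exact for small samples", {
    expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
    expect_equal(rankSumTest(c(0.2, 0.2), c(0.2, 0.2))$p_value, 1)

    ## independent enumeration of all 20 rank assignments
    r <- rank(c(1, 2, 3, 4, 5, 6))
    allW <- combn(6, 3, FUN = function(i) sum(r[i]))
    W <- sum(r[1:3])
    pEnum <- min(1, 2 * min(mean(allW <= W), mean(allW >= W)))
    expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))$p_value, pEnum)

    cmp <- compareScoreGroups(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                              rep(c("a", "b"), each = 3))
    expect_equal(cmp$p_value, 0.1)
    expect_equal(unname(cmp$group_medians), c(0.2, 0.5))
    expect_error(compareScoreGroups(c(1, 2, 3), c("a", "a", "b")),
                 "fewer than 2")
})

test_that("large samples match the reference rank-sum implementation", {
    for (s in 1:5) {
        set.seed(s)
        x <- rnorm(50); y <- rnorm(50, 0.3)
        got <- rankSumTest(x, y)$p_value
        ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
        expect_lt(abs(got - ref), 1e-6)
        expect_identical(rankSumTest(x, y)$method, "normal")
    }
})

test_that("the stage trend summarizes, tests and ranks stages", {
    ## strictly decreasing scores, one per stage rank, no ties
    tr <- stageTrend(c(3, 2, 1), c("a", "b", "c"), c("a", "b", "c"))
    expect_equal(tr$trend_r, -1)
    expect_identical(tr$perStage$stage, c("a", "b", "c"))
    expect_true(all(diff(tr$perStage$median) < 0))

    ## identical distributions: every adjacent p = 1
    tid <- stageTrend(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2),
                      c("a", "b", "c"))
    expect_true(all(tid$adjacent$p_value == 1))

    ## empty stage is skipped with a warning and recorded
    expect_warning(
        tsk <- stageTrend(c(1, 2, 3, 4), c("a", "a", "c", "c"),
                          c("a", "b", "c")),
        "skipped.*b")
    expect_identical(tsk$skipped, "b")
})

test_that("focal status uses a strict expression threshold", {
    ds <- simulateExpression(twoStageConfig(seed = 2L, nCellsPost = 4L))
    m <- SummarizedExperiment::assay(ds, "fpkm")
    st <- classifyFocalStatus(ds, "focal2")
    expect_identical(unname(st[m["focal2", ] == 0]),
                     rep("negative", sum(m["focal2", ] == 0)))
    expect_identical(unname(st[m["focal2", ] > 0]),
                     rep("positive", sum(m["focal2", ] > 0)))
    expect_error(classifyFocalStatus(ds, "nope"), "'nope' not found")

    ## binomial recovery of the TE silencing probability
    cfg <- ScrnaSimConfig(
        nEmbryos = 1L, cellsPerEmbryo = 200L, stages = "blast",
        zgaStage = "blast", sexRatio = 1, teSilencingProb = 0.5,
        biallelicFractionByStage = c(blast = 0.5),
        nPositionsPerChrom = c(X = 10L), nGenesPerChrom = c(X = 5L),
        lineageStages = "blast", lineageProbs = c(TE = 1, EPI = 0, PE = 0),
        seed = 33L)
    ds2 <- simulateExpression(cfg)
    st2 <- classifyFocalStatus(ds2, "focal2")
    expect_lt(abs(mean(st2 == "positive") - 0.5), 0.1)
})

test_that("the correlation null places the focal partner correctly", {
    ## 5-cell, 3-partner hand table against rank-correlation arithmetic
    vals <- rbind(
        tgt = c(1, 4, 2, 8, 5),
        p1 = c(2, 5, 3, 9, 6),     # monotone in tgt -> r = 1
        p2 = c(5, 1, 4, 2, 3),
        p3 = c(3, 3, 3, 3, 4))
    ds <- ExpressionDataset(
        t(vals),
        data.frame(chrom = "X", is_focal1 = c(TRUE, FALSE, FALSE, FALSE),
                   is_focal2 = FALSE, row.names = rownames(vals)),
        data.frame(cell_id = paste0("c", 1:5), embryo_id = "e1",
                   stage = "s", sex = "F", lineage = "none"))
    cn <- correlationNull(ds, "tgt", c("p1", "p2", "p3"), "p1")
    manual <- function(y) cor(rank(vals["tgt", ]), rank(y))
    expect_equal(cn@rValues[["p1"]], manual(vals["p1", ]))
    expect_equal(cn@rValues[["p2"]], manual(vals["p2", ]))
    expect_equal(cn@rValues[["p3"]], manual(vals["p3", ]))
    expect_equal(cn@focalR, 1)
    expect_equal(cn@focalQuantile, 1)

    ## a zero-variance partner is excluded and counted
    vals2 <- rbind(vals, pflat = c(7, 7, 7, 7, 7))
    ds2 <- ExpressionDataset(
        t(vals2),
        data.frame(chrom = "X", is_focal1 = c(TRUE, rep(FALSE, 4)),
                   is_focal2 = FALSE, row.names = rownames(vals2)),
        data.frame(cell_id = paste0("c", 1:5), embryo_id = "e1",
                   stage = "s", sex = "F", lineage = "none"))
    cn2 <- correlationNull(ds2, "tgt", c("p1", "p2", "p3", "pflat"), "p1")
    expect_identical(cn2@nExcluded, 1L)
    expect_identical(sort(names(cn2@rValues)), c("p1", "p2", "p3"))

    expect_error(correlationNull(ds, "tgt", c("p1", "p2"), "p3"), "member")
    expect_error(correlationNull(ds, "tgt", character(0), "p1"), "nonempty")
    expect_error(correlationNull(ds, "tgt", c("p1", "p2"), "p1",
                                 cellFilter = c("c1", "c2")), "3 cells")
})

test_that("gene-level allelic calls pool positions and compare conditions", {
    mkRec <- function(cell, gene, pos, ref, alt)
        data.frame(cell_id = cell, chrom = "X", pos = pos, gene = gene,
                   ref_count = ref, alt_count = alt)
    recs <- rbind(
        ## gene gBi: two informative positions, both balanced across cells
        mkRec("c1", "gBi", 1L, 5L, 5L), mkRec("c2", "gBi", 1L, 6L, 4L),
        mkRec("c1", "gBi", 2L, 4L, 6L),
        ## gene gMono: two informative positions, one-sided
        mkRec("c1", "gMono", 11L, 10L, 0L), mkRec("c2", "gMono", 11L, 8L, 0L),
        mkRec("c1", "gMono", 12L, 9L, 0L),
        ## gene gThin: a single informative position -> uninformative
        mkRec("c1", "gThin", 21L, 5L, 5L))
    calls <- geneAllelicCalls(AlleleCountTable(recs),
                              CallParams(0.2, 5L, 1L),
                              perGeneMinPositions = 2L)
    expect_identical(calls$call[calls$gene == "gBi"], "biallelic")
    expect_identical(calls$call[calls$gene == "gMono"], "monoallelic")
    expect_identical(calls$call[calls$gene == "gThin"], "uninformative")

    ## condition comparison builds the mono/bi 2x2 and tests it exactly
    conds <- c(c1 = "naive", c2 = "primed")
    out <- geneAllelicCalls(AlleleCountTable(recs), CallParams(0.2, 5L, 1L),
                            conditions = conds, perGeneMinPositions = 1L)
    expect_identical(dim(out$table), c(2L, 2L))
    expect_equal(out$p_value, fisher.test(out$table)$p.value)
    expect_error(
        geneAllelicCalls(AlleleCountTable(mkRec("c1", "g", 1L, 1L, 1L)),
                         CallParams(0.2, 5L, 1L),
                         conditions = c(c1 = "a", cX = "b")),
        "no informative genes")
})
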