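test_that("identical configurations reproduce identical datasets", {
    cfg <- twoStageConfig(seed = 42L)
    d1 <- simulateExpression(cfg); d2 <- simulateExpression(cfg)
    expect_identical(SummarizedExperiment::assay(d1, "fpkm"),
                     SummarizedExperiment::assay(d2, "fpkm"))
    t1 <- simulateAlleleCounts(d1, cfg); t2 <- simulateAlleleCounts(d2, cfg)
    expect_identical(alleleRecords(t1), alleleRecords(t2))
    expect_identical(alleleTruth(t1), alleleTruth(t2))
})

test_that("focal genes are silent before ZGA and on afterwards", {
    cfg <- twoStageConfig(seed = 5L)
    ds <- simulateExpression(cfg)
    e <- SummarizedExperiment::assay(ds, "fpkm")
    cd <- SummarizedExperiment::colData(ds)
    pre <- cd$stage == "pre"
    expect_true(all(e["focal1", pre] == 0))
    expect_true(all(e["focal2", pre] == 0))    # maternal trace off by default
    expect_true(all(e["focal1", !pre] > 0))

    cfgTrace <- twoStageConfig(seed = 5L)
    cfgTrace@maternalTrace <- 0.005
    eT <- SummarizedExperiment::assay(simulateExpression(cfgTrace), "fpkm")
    expect_true(all(eT["focal2", pre] == 0.005))
    expect_true(all(eT["focal1", pre] == 0))
})

test_that("the copula hits the target focal Spearman correlation", {
    cfg <- twoStageConfig(seed = 8L, nCellsPost = 300L, rho = 0.9)
    ds <- simulateExpression(cfg)
    e <- SummarizedExperiment::assay(ds, "fpkm")
    post <- SummarizedExperiment::colData(ds)$stage == "post"
    r <- cor(e["focal1", post], e["focal2", post], method = "spearman")
    expect_gte(r, 0.82)
    expect_lte(r, 0.95)
    ## independence regime: |r| stays small
    for (s in 1:3) {
        cfg0 <- twoStageConfig(seed = 100L + s, nCellsPost = 300L, rho = 0)
        ds0 <- simulateExpression(cfg0)
        e0 <- SummarizedExperiment::assay(ds0, "fpkm")
        p0 <- SummarizedExperiment::colData(ds0)$stage == "post"
        expect_lt(abs(cor(e0["focal1", p0], e0["focal2", p0],
                          method = "spearman")), 0.15)
    }
})

test_that("trophectoderm silencing switches focal gene 2 off, not gene 1", {
    cfg <- ScrnaSimConfig(
        nEmbryos = 2L, cellsPerEmbryo = 50L, stages = c("pre", "blast"),
        zgaStage = "blast", sexRatio = 1, teSilencingProb = 1,
        biallelicFractionByStage = c(pre = 0.5, blast = 0.5),
        nPositionsPerChrom = c(X = 20L), nGenesPerChrom = c(X = 10L),
        lineageStages = "blast", lineageProbs = c(TE = 1, EPI = 0, PE = 0),
        seed = 9L)
    ds <- simulateExpression(cfg)
    e <- SummarizedExperiment::assay(ds, "fpkm")
    cd <- SummarizedExperiment::colData(ds)
    te <- cd$lineage == "TE"
    expect_true(any(te))
    expect_true(all(e["focal2", te] == 0))
    expect_true(all(e["focal1", te] > 0))
})

test_that("male cells never yield bi-allelic X positions", {
    cfg <- twoStageConfig(seed = 3L, sexRatio = 0)
    ds <- simulateExpression(cfg)
    tab <- simulateAlleleCounts(ds, cfg)
    r <- alleleRecords(tab)
    x <- r[r$chrom == "X", ]
    expect_gt(nrow(x), 0)
    expect_true(all(pmin(x$ref_count, x$alt_count) == 0))
    tr <- alleleTruth(tab)
    expect_false(any(tr$true_biallelic[tr$chrom == "X"]))
})

test_that("bi-allelic call rate matches the binomial-tail expectation", {
    cfg <- ScrnaSimConfig(
        nEmbryos = 1L, cellsPerEmbryo = 50L, stages = "E4", zgaStage = "E4",
        sexRatio = 1, biallelicFractionByStage = c(E4 = 0.5),
        nPositionsPerChrom = c(X = 200L), nGenesPerChrom = c(X = 20L),
        lineageStages = "E4", lineageProbs = c(TE = 0, EPI = 0, PE = 0),
        seed = 21L)
    tab <- simulateAlleleCounts(simulateExpression(cfg), cfg)
    r <- alleleRecords(tab)
    x <- r$chrom == "X"
    depth <- (r$ref_count + r$alt_count)[x]
    ratio <- allelicRatio(tab)[x]
    ## P(minor fraction >= 0.2 | balanced binomial at this depth), per record
    pTail <- vapply(depth, function(d) {
        k <- 0:d
        sum(dbinom(k, d, 0.5)[pmin(k, d - k) / d >= 0.2])
    }, 0)
    expected <- mean(0.5 * pTail)       # latent bi-allelic probability 0.5
    observed <- mean(ratio >= 0.2)
    expect_lt(abs(observed - expected), 0.07)
})

test_that("stage-decreasing ground truth is strictly decreasing", {
    fr <- c(s1 = 0.6, s2 = 0.45, s3 = 0.3, s4 = 0.1)
    cfg <- stageSeriesConfig(seed = 31L, fractions = fr, cellsPerStage = 30L)
    tab <- simulateAlleleCounts(simulateExpression(cfg), cfg)
    tr <- alleleTruth(tab)
    tr <- tr[tr$chrom == "X", ]
    stage <- sub("^emb[0-9]+_([^_]+)_.*$", "\\1", tr$cell_id)
    m <- tapply(tr$true_biallelic, stage, mean)[names(fr)]
    expect_true(all(diff(m) < 0))
})

test_that("dataset bundles round-trip losslessly (TSV and MTX)", {
    cfg <- twoStageConfig(seed = 13L, nCellsPost = 5L)
    ds <- simulateExpression(cfg)
    tab <- simulateAlleleCounts(ds, cfg)
    for (fmt in c("tsv", "mtx")) {
        dir <- file.path(tempfile(), fmt)
        writeScrnaDataset(ds, tab, dir, format = fmt)
        back <- readScrnaDataset(dir)
        expect_equal(SummarizedExperiment::assay(back$dataset, "fpkm"),
                     SummarizedExperiment::assay(ds, "fpkm"))
        expect_identical(
            as.data.frame(SummarizedExperiment::colData(back$dataset)),
            as.data.frame(SummarizedExperiment::colData(ds)))
        expect_identical(stageLevels(back$dataset), stageLevels(ds))
        expect_identical(alleleRecords(back$table), alleleRecords(tab))
        expect_equal(alleleTruth(back$table)$true_biallelic,
                     alleleTruth(tab)$true_biallelic)
    }
})

test_that("malformed allele tables raise parse errors naming the line", {
    dir <- tempfile(); dir.create(dir)
    p <- file.path(dir, "ac.tsv")
    hdr <- "chrom\tpos\tgene\tcell_id\tref_count\talt_count"

    writeLines(c(hdr, "X\t10\tg1\tc1\t2.5\t3"), p)
    expect_error(readAlleleCounts(p), "line 2.*ref_count.*2\\.5")

    writeLines(c(hdr, "X\t10\tg1\tc1\t2\t3", "X\t10\tg1\tc1\t4\t5"), p)
    expect_error(readAlleleCounts(p), "line 3.*duplicate")

    writeLines("chrom\tpos\tgene", p)
    expect_error(readAlleleCounts(p), "malformed header")

    writeLines(hdr, p)                 # empty body is fine
    empty <- readAlleleCounts(p)
    expect_s4_class(empty, "AlleleCountTable")
    expect_identical(nrow(empty), 0L)
})

test_that("VCF import reads per-sample AD fields", {
    skip_if_not_installed("vcfR")
    p <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcellA\tcellB",
        "X\t101\t.\tA\tG\t.\tPASS\tGENE=xg1\tGT:AD\t0/1:7,5\t0/1:9,0",
        "7\t55\t.\tC\tT\t.\tPASS\tGENE=ag1\tGT:AD\t0/1:3,3\t0/1:2,8"), p)
    tab <- readAlleleCountsVCF(p)
    r <- alleleRecords(tab)
    expect_identical(nrow(r), 4L)
    cellA_X <- r[r$cell_id == "cellA" & r$chrom == "X", ]
    expect_identical(cellA_X$ref_count, 7L)
    expect_identical(cellA_X$alt_count, 5L)
    expect_identical(cellA_X$gene, "xg1")
    expect_identical(cellA_X$pos, 101L)
})

test_that("configuration validity is enforced", {
    expect_error(ScrnaSimConfig(focalRho = 1.5), "focalRho")
    expect_error(ScrnaSimConfig(stages = character(0)), "nonempty")
    expect_error(ScrnaSimConfig(sexRatio = 1.2), "\\[0,1\\]")
    expect_error(
        ScrnaSimConfig(biallelicFractionByStage = c(nosuch = 0.5)), "subset")
    cfg <- twoStageConfig()
    bad <- twoStageConfig()
    bad@biallelicFractionByStage <- c(pre = 0.5)    # 'post' missing
    ds <- simulateExpression(cfg)
    expect_error(simulateAlleleCounts(ds, bad), "stage 'post'")
})
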