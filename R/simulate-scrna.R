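#' @importFrom stats rlnorm rnorm rbinom rnbinom runif cor median quantile
#'   pnorm sd setNames
NULL

## Spearman rho -> Pearson correlation of the underlying Gaussian copula
copulaRho <- function(spearman) 2 * sin(pi * spearman / 6)

#' Simulate a per-cell expression matrix with embryo structure
#'
#' Generates an FPKM-scale cells x genes matrix following the developmental
#' logic of human pre-implantation embryos: both focal X-linked genes are off
#' (focal gene 2 optionally at a maternal trace level) strictly before the ZGA
#' stage; from the ZGA stage on, their log expression is drawn from a Gaussian
#' copula tuned so the Spearman correlation across cells matches
#' \code{focalRho}; trophectoderm cells then silence focal gene 2 with
#' probability \code{teSilencingProb} while focal gene 1 stays on. Background
#' genes are independent log-normal draws. All randomness is fixed by
#' \code{config@seed}.
#'
#' @param config a [ScrnaSimConfig-class].
#' @return an [ExpressionDataset-class] whose \code{rowData} flags the focal
#'   genes and whose \code{colData} carries embryo id, stage, sex and lineage.
#' @examples
#' ds <- simulateExpression(ScrnaSimConfig(seed = 11))
#' ds
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "ScrnaSimConfig"))
    validObject(config)
    set.seed(config@seed)
    stages <- config@stages
    nS <- length(stages)

    embryoStage <- stages[((seq_len(config@nEmbryos) - 1L) %% nS) + 1L]
    embryoSex <- ifelse(runif(config@nEmbryos) < config@sexRatio, "F", "M")

    nCellsOf <- function(stage) {
        cpe <- config@cellsPerEmbryo
        if (is.null(names(cpe))) cpe[1L]
        else if (stage %in% names(cpe)) cpe[[stage]]
        else stop("no cells-per-embryo entry for stage '", stage, "'")
    }
    cellMeta <- do.call(rbind, lapply(seq_len(config@nEmbryos), function(e) {
        n <- nCellsOf(embryoStage[e])
        data.frame(
            cell_id = sprintf("emb%02d_%s_c%02d", e, embryoStage[e], seq_len(n)),
            embryo_id = sprintf("emb%02d", e),
            stage = embryoStage[e], sex = embryoSex[e],
            lineage = "none", stringsAsFactors = FALSE)
    }))
    nCells <- nrow(cellMeta)

    ## blastocyst lineages only at the configured (post-ZGA) stages
    inLin <- cellMeta$stage %in% config@lineageStages
    if (any(inLin)) {
        pr <- config@lineageProbs
        cellMeta$lineage[inLin] <- sample(
            c(names(pr), "none"), sum(inLin), replace = TRUE,
            prob = c(pr, max(0, 1 - sum(pr))))
    }

    chroms <- names(config@nGenesPerChrom)
    bgIds <- unlist(lapply(chroms, function(ch)
        sprintf("g%s_%03d", ch, seq_len(config@nGenesPerChrom[[ch]]))))
    bgChrom <- rep(chroms, config@nGenesPerChrom)
    geneMeta <- data.frame(
        chrom = c("X", "X", bgChrom),
        is_focal1 = c(TRUE, FALSE, rep(FALSE, length(bgIds))),
        is_focal2 = c(FALSE, TRUE, rep(FALSE, length(bgIds))),
        marker = "none",
        row.names = c("focal1", "focal2", bgIds), stringsAsFactors = FALSE)

    stageRank <- match(cellMeta$stage, stages)
    zgaRank <- match(config@zgaStage, stages)
    post <- stageRank >= zgaRank

    values <- matrix(0, nrow = nCells, ncol = nrow(geneMeta),
                     dimnames = list(cellMeta$cell_id, rownames(geneMeta)))

    ## focal pair: Gaussian copula on log expression for post-ZGA cells
    nPost <- sum(post)
    if (nPost > 0L) {
        rho <- copulaRho(config@focalRho)
        z1 <- rnorm(nPost)
        z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(nPost)
        values[post, "focal1"] <- exp(config@exprLogmean + config@exprLogsd * z1)
        values[post, "focal2"] <- exp(config@exprLogmean + config@exprLogsd * z2)
    }
    values[!post, "focal2"] <- config@maternalTrace

    isTE <- cellMeta$lineage == "TE"
    if (any(isTE)) {
        off <- isTE & (runif(nCells) < config@teSilencingProb)
        values[off, "focal2"] <- 0
    }

    values[, bgIds] <- matrix(
        rlnorm(nCells * length(bgIds), config@exprLogmean, config@exprLogsd),
        nrow = nCells)

    ExpressionDataset(values, geneMeta, cellMeta, stages = stages)
}

#' Simulate per-cell allele counts at heterozygous positions
#'
#' For every cell and heterozygous position, total read depth is drawn from a
#' negative binomial (\code{coverageMean}, \code{coverageDispersion}); a
#' latent indicator marks the position bi-allelic in that cell. On the X
#' chromosome of female cells the indicator probability is the stage's entry
#' of \code{biallelicFractionByStage}; male X positions are always
#' mono-allelic; autosomes use the flat \code{autosomalBiallelicFraction}.
#' Bi-allelic positions split their reads by a balanced binomial; mono-allelic
#' positions send all reads to one random allele. An optional symmetric
#' per-read flip (\code{errorRate}) can then corrupt either class. Zero-depth
#' records are dropped. The latent indicators are retained in the table's
#' \code{truth} slot.
#'
#' @param dataset an [ExpressionDataset-class] supplying cells and genes.
#' @param config the [ScrnaSimConfig-class] used to generate it.
#' @return an [AlleleCountTable-class] with ground truth.
#' @examples
#' cfg <- ScrnaSimConfig(seed = 11, nPositionsPerChrom = c(X = 40L, "7" = 40L))
#' tab <- simulateAlleleCounts(simulateExpression(cfg), cfg)
#' tab
#' @export
simulateAlleleCounts <- function(dataset, config) {
    stopifnot(is(dataset, "ExpressionDataset"), is(config, "ScrnaSimConfig"))
    cd <- as.data.frame(SummarizedExperiment::colData(dataset))
    bf <- config@biallelicFractionByStage
    missingStage <- setdiff(unique(cd$stage), names(bf))
    if ("X" %in% names(config@nPositionsPerChrom) && length(missingStage))
        stop("no bi-allelic fraction configured for stage '",
             missingStage[1L], "'")

    set.seed(as.integer((config@seed + 999983) %% .Machine$integer.max))
    rd <- as.data.frame(SummarizedExperiment::rowData(dataset))
    geneIds <- rownames(rd)

    recs <- vector("list", length(config@nPositionsPerChrom))
    for (k in seq_along(config@nPositionsPerChrom)) {
        ch <- names(config@nPositionsPerChrom)[k]
        npos <- config@nPositionsPerChrom[[k]]
        genesOnChrom <- geneIds[rd$chrom == ch]
        if (!length(genesOnChrom))
            stop("no genes on chromosome '", ch, "' to anchor positions")
        pos <- sort(sample.int(1e8L, npos))
        posGene <- genesOnChrom[((seq_len(npos) - 1L) %% length(genesOnChrom)) + 1L]

        n <- nrow(cd) * npos
        df <- data.frame(
            cell_id = rep(cd$cell_id, each = npos),
            chrom = ch,
            pos = rep(pos, times = nrow(cd)),
            gene = rep(posGene, times = nrow(cd)),
            stringsAsFactors = FALSE)
        stage <- rep(cd$stage, each = npos)
        sex <- rep(cd$sex, each = npos)

        depth <- rnbinom(n, size = config@coverageDispersion,
                         mu = config@coverageMean)
        if (ch == "X") {
            p <- ifelse(sex == "F", bf[stage], 0)
        } else {
            p <- rep(config@autosomalBiallelicFraction, n)
        }
        latent <- runif(n) < p
        ref <- integer(n)
        ref[latent] <- rbinom(sum(latent), depth[latent], 0.5)
        ## the expressed allele of a mono-allelic position is fixed per
        ## position (not per cell): pooled-condition gene calls then behave
        ## like clonal or skewed samples, where the same haplotype is
        ## silenced in every cell
        refAll <- rep(runif(npos) < 0.5, times = nrow(cd))
        ref[!latent] <- ifelse(refAll[!latent], depth[!latent], 0L)
        alt <- depth - ref
        if (config@errorRate > 0) {
            r2a <- rbinom(n, ref, config@errorRate)
            a2r <- rbinom(n, alt, config@errorRate)
            ref <- ref - r2a + a2r
            alt <- depth - ref
        }
        df$ref_count <- as.integer(ref)
        df$alt_count <- as.integer(alt)
        df$true_biallelic <- latent
        recs[[k]] <- df[depth > 0L, , drop = FALSE]
    }
    all <- do.call(rbind, recs)
    rownames(all) <- NULL
    truth <- all[, c("cell_id", "chrom", "pos", "gene", "true_biallelic")]
    AlleleCountTable(all[, c("cell_id", "chrom", "pos", "gene",
                             "ref_count", "alt_count")],
                     truth = truth)
}
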