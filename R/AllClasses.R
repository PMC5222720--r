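#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Simulation configuration for the single-cell RNA-seq arm
## ---------------------------------------------------------------------------

#' Configuration for the single-cell RNA-seq simulator
#'
#' Holds every parameter of the generative model for per-cell expression and
#' allele-specific read counts across an early-embryo developmental series:
#' embryo/stage layout, the zygotic-genome-activation (ZGA) stage at which the
#' two focal X-linked lncRNA genes (XIST-like and XACT-like) switch on, the
#' target rank correlation of the two focal genes after ZGA, lineage-specific
#' silencing of focal gene 2 in trophectoderm, the per-stage expected fraction
#' of bi-allelically expressed heterozygous X positions in female cells, and
#' the negative-binomial read-depth model.
#'
#' @slot nEmbryos number of embryos; embryos are assigned to stages round-robin
#'   in stage order, so multiples of \code{length(stages)} give balanced series.
#' @slot cellsPerEmbryo integer count, or named integer vector keyed by stage.
#' @slot stages ordered character vector of developmental stage labels.
#' @slot sexRatio probability that an embryo is female, in [0,1].
#' @slot zgaStage stage label at which the focal genes switch on.
#' @slot focalRho target Spearman correlation of the focal genes after ZGA,
#'   in [-1,1]; induced through a Gaussian copula on log expression.
#' @slot teSilencingProb probability that a trophectoderm cell silences focal
#'   gene 2 (expression set to 0) while focal gene 1 stays on.
#' @slot biallelicFractionByStage named numeric, stage -> expected fraction of
#'   heterozygous X positions that are bi-allelic in female cells at that stage.
#' @slot autosomalBiallelicFraction stage-independent bi-allelic fraction used
#'   for every non-X chromosome.
#' @slot nPositionsPerChrom named integer, chromosome -> number of heterozygous
#'   positions simulated.
#' @slot nGenesPerChrom named integer, chromosome -> number of background genes.
#' @slot coverageMean,coverageDispersion negative-binomial mean and size for
#'   per-position read depth.
#' @slot exprLogmean,exprLogsd log-normal parameters (natural log) of the
#'   FPKM-scale expression marginals.
#' @slot maternalTrace expression level of focal gene 2 before ZGA (maternal
#'   contribution); 0 disables it.
#' @slot errorRate symmetric per-read allele flip probability (sequencing /
#'   alignment error); default 0.
#' @slot lineageStages stages at which blastocyst lineages (TE/EPI/PE) are
#'   assigned; must be at or after \code{zgaStage}.
#' @slot lineageProbs named numeric over c("TE","EPI","PE"), summing to <= 1
#'   (remainder stays "none").
#' @slot seed integer seed fixing all randomness of both generators.
#'
#' @seealso [simulateExpression()], [simulateAlleleCounts()]
#' @export
setClass("ScrnaSimConfig",
    representation(
        nEmbryos = "integer",
        cellsPerEmbryo = "integer",
        stages = "character",
        sexRatio = "numeric",
        zgaStage = "character",
        focalRho = "numeric",
        teSilencingProb = "numeric",
        biallelicFractionByStage = "numeric",
        autosomalBiallelicFraction = "numeric",
        nPositionsPerChrom = "integer",
        nGenesPerChrom = "integer",
        coverageMean = "numeric",
        coverageDispersion = "numeric",
        exprLogmean = "numeric",
        exprLogsd = "numeric",
        maternalTrace = "numeric",
        errorRate = "numeric",
        lineageStages = "character",
        lineageProbs = "numeric",
        seed = "integer"
    )
)

setValidity("ScrnaSimConfig", function(object) {
    msg <- character()
    if (length(object@stages) == 0L)
        msg <- c(msg, "'stages' must be a nonempty ordered vector of labels")
    if (anyDuplicated(object@stages))
        msg <- c(msg, "'stages' must not contain duplicates")
    prb <- c(sexRatio = object@sexRatio, teSilencingProb = object@teSilencingProb,
             autosomalBiallelicFraction = object@autosomalBiallelicFraction,
             errorRate = object@errorRate)
    bad <- names(prb)[prb < 0 | prb > 1]
    if (length(bad))
        msg <- c(msg, paste0("probabilities must lie in [0,1]: ",
                             paste(bad, collapse = ", ")))
    if (abs(object@focalRho) > 1)
        msg <- c(msg, "'focalRho' must lie in [-1,1]")
    bf <- object@biallelicFractionByStage
    if (any(bf < 0 | bf > 1))
        msg <- c(msg, "'biallelicFractionByStage' values must lie in [0,1]")
    if (!all(names(bf) %in% object@stages))
        msg <- c(msg, "'biallelicFractionByStage' keys must be a subset of 'stages'")
    if (!(object@zgaStage %in% object@stages))
        msg <- c(msg, "'zgaStage' must be one of 'stages'")
    zi <- match(object@zgaStage, object@stages)
    if (!all(match(object@lineageStages, object@stages) >= zi))
        msg <- c(msg, "'lineageStages' must be at or after 'zgaStage'")
    if (sum(object@lineageProbs) > 1 + 1e-8 || any(object@lineageProbs < 0))
        msg <- c(msg, "'lineageProbs' must be nonnegative and sum to at most 1")
    if (!setequal(names(object@lineageProbs), c("TE", "EPI", "PE")))
        msg <- c(msg, "'lineageProbs' must be named TE, EPI, PE")
    if (object@coverageMean <= 0 || object@coverageDispersion <= 0)
        msg <- c(msg, "coverage parameters must be positive")
    if (is.null(names(object@nPositionsPerChrom)) ||
        is.null(names(object@nGenesPerChrom)))
        msg <- c(msg, "'nPositionsPerChrom' and 'nGenesPerChrom' must be named by chromosome")
    if (length(msg)) msg else TRUE
})

#' Create a single-cell RNA-seq simulation configuration
#'
#' Defaults describe a human pre-implantation series: the two focal X-linked
#' genes switch on at the 8-cell stage (ZGA), are strongly rank-correlated
#' afterwards, and the fraction of bi-allelic X positions in female cells
#' erodes over the blastocyst stages as X inactivation initiates, while
#' autosomal bi-allelic fractions stay flat.
#'
#' @param nEmbryos,cellsPerEmbryo embryo layout (embryos cycle over stages).
#' @param stages ordered stage labels.
#' @param sexRatio fraction of female embryos.
#' @param zgaStage stage at which focal genes switch on.
#' @param focalRho target post-ZGA Spearman correlation of the focal genes.
#' @param teSilencingProb probability a TE cell silences focal gene 2.
#' @param biallelicFractionByStage named stage -> fraction map for X in females.
#' @param autosomalBiallelicFraction flat bi-allelic fraction on autosomes.
#' @param nPositionsPerChrom,nGenesPerChrom named per-chromosome counts.
#' @param coverageMean,coverageDispersion negative-binomial depth parameters.
#' @param exprLogmean,exprLogsd log-normal expression parameters.
#' @param maternalTrace pre-ZGA expression of focal gene 2 (0 = off).
#' @param errorRate symmetric per-read allele flip probability.
#' @param lineageStages,lineageProbs blastocyst lineage assignment.
#' @param seed integer seed.
#' @return a [ScrnaSimConfig-class] object.
#' @examples
#' cfg <- ScrnaSimConfig(seed = 7)
#' cfg
#' @export
ScrnaSimConfig <- function(
        nEmbryos = 14L,
        cellsPerEmbryo = 10L,
        stages = c("oocyte", "2cell", "4cell", "8cell", "morula",
                   "earlyblast", "lateblast"),
        sexRatio = 0.5,
        zgaStage = "8cell",
        focalRho = 0.7,
        teSilencingProb = 0.5,
        biallelicFractionByStage = c(oocyte = 0.5, "2cell" = 0.5, "4cell" = 0.5,
                                     "8cell" = 0.5, morula = 0.5,
                                     earlyblast = 0.4, lateblast = 0.2),
        autosomalBiallelicFraction = 0.5,
        nPositionsPerChrom = c(X = 200L, "7" = 200L),
        nGenesPerChrom = c(X = 60L, "7" = 60L),
        coverageMean = 20,
        coverageDispersion = 2,
        exprLogmean = 1,
        exprLogsd = 1,
        maternalTrace = 0,
        errorRate = 0,
        lineageStages = utils::tail(stages, 1L),
        lineageProbs = c(TE = 0.5, EPI = 0.3, PE = 0.2),
        seed = 1L) {
    if (!is.null(names(cellsPerEmbryo)) &&
        !all(names(cellsPerEmbryo) %in% stages))
        stop("names of 'cellsPerEmbryo' must be stage labels")
    cpe <- as.integer(cellsPerEmbryo)
    names(cpe) <- names(cellsPerEmbryo)
    npos <- as.integer(nPositionsPerChrom)
    names(npos) <- names(nPositionsPerChrom)
    ngen <- as.integer(nGenesPerChrom)
    names(ngen) <- names(nGenesPerChrom)
    new("ScrnaSimConfig",
        nEmbryos = as.integer(nEmbryos), cellsPerEmbryo = cpe,
        stages = as.character(stages), sexRatio = sexRatio,
        zgaStage = zgaStage, focalRho = focalRho,
        teSilencingProb = teSilencingProb,
        biallelicFractionByStage = biallelicFractionByStage,
        autosomalBiallelicFraction = autosomalBiallelicFraction,
        nPositionsPerChrom = npos, nGenesPerChrom = ngen,
        coverageMean = coverageMean, coverageDispersion = coverageDispersion,
        exprLogmean = exprLogmean, exprLogsd = exprLogsd,
        maternalTrace = maternalTrace, errorRate = errorRate,
        lineageStages = lineageStages, lineageProbs = lineageProbs,
        seed = as.integer(seed))
}

setMethod("show", "ScrnaSimConfig", function(object) {
    cat("ScrnaSimConfig\n")
    cat("  stages:", paste(object@stages, collapse = " > "), "\n")
    cat("  embryos:", object@nEmbryos, " cells/embryo:",
        paste(object@cellsPerEmbryo, collapse = ","), "\n")
    cat("  ZGA at:", object@zgaStage, " focal Spearman target:",
        object@focalRho, "\n")
    cat("  chroms:", paste(names(object@nPositionsPerChrom), collapse = ", "),
        " seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## ExpressionDataset: cells x genes FPKM-scale matrix on SummarizedExperiment
## ---------------------------------------------------------------------------

#' Per-cell expression with embryo metadata
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"fpkm"}
#' (genes in rows, cells in columns), gene annotation in \code{rowData}
#' (\code{chrom}, \code{is_focal1}, \code{is_focal2}, \code{marker}) and cell
#' annotation in \code{colData} (\code{cell_id}, \code{embryo_id},
#' \code{stage}, \code{sex}, \code{lineage}). The ordered stage labels are
#' kept in \code{metadata(x)$stages}.
#'
#' @seealso [ExpressionDataset()], [simulateExpression()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        return("assay 'fpkm' is required")
    a <- SummarizedExperiment::assay(object, "fpkm")
    if (any(a < 0)) msg <- c(msg, "expression values must be nonnegative")
    cd <- SummarizedExperiment::colData(object)
    need <- c("cell_id", "embryo_id", "stage", "sex", "lineage")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
    else {
        if (anyNA(cd$stage)) msg <- c(msg, "every cell must carry a stage")
        if (!all(cd$sex %in% c("F", "M")))
            msg <- c(msg, "sex must be 'F' or 'M'")
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("chrom", "is_focal1", "is_focal2") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain chrom, is_focal1, is_focal2")
    else if (any((rd$is_focal1 | rd$is_focal2) & rd$chrom != "X"))
        msg <- c(msg, "focal genes must be X-linked")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, cells in rows and genes in columns (the
#'   user-facing orientation; stored transposed, genes x cells).
#' @param geneMeta data.frame with columns \code{chrom}, \code{is_focal1},
#'   \code{is_focal2} and optionally \code{marker}; rownames are gene ids.
#' @param cellMeta data.frame with columns \code{cell_id}, \code{embryo_id},
#'   \code{stage}, \code{sex}, \code{lineage}.
#' @param stages ordered stage labels (defaults to order of appearance).
#' @return an [ExpressionDataset-class].
#' @export
ExpressionDataset <- function(values, geneMeta, cellMeta,
                              stages = unique(cellMeta$stage)) {
    if (!"marker" %in% colnames(geneMeta)) geneMeta$marker <- "none"
    m <- t(as.matrix(values))
    rownames(m) <- rownames(geneMeta)
    colnames(m) <- cellMeta$cell_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = m),
        rowData = S4Vectors::DataFrame(geneMeta),
        colData = S4Vectors::DataFrame(cellMeta, row.names = cellMeta$cell_id),
        metadata = list(stages = stages))
    new("ExpressionDataset", se)
}

#' @describeIn ExpressionDataset ordered stage labels of a dataset.
#' @param x an ExpressionDataset.
#' @export
stageLevels <- function(x) S4Vectors::metadata(x)$stages

#' @describeIn ExpressionDataset gene ids of the two focal genes
#'   (focal1 = XIST-like, focal2 = XACT-like).
#' @export
focalGenes <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    c(focal1 = rownames(x)[which(rd$is_focal1)[1L]],
      focal2 = rownames(x)[which(rd$is_focal2)[1L]])
}

setMethod("show", "ExpressionDataset", function(object) {
    cat("ExpressionDataset:", nrow(object), "genes x", ncol(object), "cells\n")
    cat("  stages:", paste(stageLevels(object), collapse = " > "), "\n")
    cat("  focal genes:", paste(focalGenes(object), collapse = ", "), "\n")
    tb <- table(SummarizedExperiment::colData(object)$sex)
    cat("  sex:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## AlleleCountTable
## ---------------------------------------------------------------------------

#' Per-cell allele counts at heterozygous positions
#'
#' Records of reference/alternative read counts per (cell, chromosome,
#' position), with the gene each position falls in. The derived allelic ratio
#' is the minor-allele read fraction \code{min(ref,alt)/(ref+alt)}, defined
#' only at positions with at least one read. When the table comes from the
#' simulator, the latent per-record bi-allelic indicators are retained in the
#' \code{truth} slot for recovery tests.
#'
#' @slot records data.frame with columns \code{cell_id}, \code{chrom},
#'   \code{pos} (1-based), \code{gene}, \code{ref_count}, \code{alt_count}.
#' @slot truth data.frame with the same keys plus \code{true_biallelic}
#'   (logical ground truth); zero rows when unknown.
#' @seealso [simulateAlleleCounts()], [callBiallelic()], [allelicRatio()]
#' @export
setClass("AlleleCountTable",
    representation(records = "data.frame", truth = "data.frame"))

setValidity("AlleleCountTable", function(object) {
    r <- object@records
    need <- c("cell_id", "chrom", "pos", "gene", "ref_count", "alt_count")
    if (!all(need %in% colnames(r)))
        return(paste("records must contain:", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(r)) {
        if (any(r$ref_count < 0) || any(r$alt_count < 0))
            msg <- c(msg, "counts must be nonnegative")
        if (any(r$ref_count != round(r$ref_count)) ||
            any(r$alt_count != round(r$alt_count)))
            msg <- c(msg, "counts must be integers")
        if (anyDuplicated(r[, c("cell_id", "chrom", "pos")]))
            msg <- c(msg, "(cell_id, chrom, pos) must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AlleleCountTable
#' @param records data.frame of per-cell per-position allele counts.
#' @param truth optional data.frame of latent bi-allelic indicators.
#' @return an [AlleleCountTable-class].
#' @export
AlleleCountTable <- function(records, truth = records[0, , drop = FALSE]) {
    records <- as.data.frame(records)
    if (nrow(records)) {
        records$pos <- as.integer(records$pos)
        records$ref_count <- as.integer(records$ref_count)
        records$alt_count <- as.integer(records$alt_count)
        records$chrom <- as.character(records$chrom)
    }
    new("AlleleCountTable", records = records, truth = as.data.frame(truth))
}

#' @describeIn AlleleCountTable the records data.frame.
#' @param x an AlleleCountTable.
#' @export
alleleRecords <- function(x) x@records

#' @describeIn AlleleCountTable latent ground-truth indicators (may be empty).
#' @export
alleleTruth <- function(x) x@truth

#' Minor-allele read fraction per record
#'
#' \code{min(ref,alt)/(ref+alt)}; \code{NA} where the position has no reads.
#' Always in [0, 0.5] where defined.
#' @param x an [AlleleCountTable-class].
#' @return numeric vector aligned with \code{alleleRecords(x)}.
#' @export
allelicRatio <- function(x) {
    r <- x@records
    tot <- r$ref_count + r$alt_count
    out <- ifelse(tot > 0, pmin(r$ref_count, r$alt_count) / tot, NA_real_)
    as.numeric(out)
}

setMethod("show", "AlleleCountTable", function(object) {
    r <- object@records
    cat("AlleleCountTable:", nrow(r), "records,",
        length(unique(r$cell_id)), "cells,",
        length(unique(r$chrom)), "chromosomes\n")
    if (nrow(object@truth))
        cat("  ground truth available (", nrow(object@truth), "records )\n")
})

#' @export
setMethod("nrow", "AlleleCountTable", function(x) nrow(x@records))

## ---------------------------------------------------------------------------
## CallParams and BiallelicSummary
## ---------------------------------------------------------------------------

#' Parameters for bi-allelic position calling
#'
#' @slot ratioThreshold minor-allele ratio threshold in (0, 0.5]; a covered
#'   position is called bi-allelic when its ratio is >= this value (inclusive).
#' @slot minTotalReads minimum read depth for a position to count as covered.
#' @slot minPositions minimum covered positions per (cell, chromosome) for the
#'   score to be defined; below it the score is flagged missing, never 0.
#' @slot normalization \code{"positions"} (bi-allelic count / covered-position
#'   count, the default) or \code{"reads"} (bi-allelic count / total covered
#'   read depth).
#' @export
setClass("CallParams",
    representation(ratioThreshold = "numeric", minTotalReads = "integer",
                   minPositions = "integer", normalization = "character"))

setValidity("CallParams", function(object) {
    msg <- character()
    if (object@ratioThreshold <= 0 || object@ratioThreshold > 0.5)
        msg <- c(msg, "'ratioThreshold' must lie in (0, 0.5]")
    if (object@minTotalReads < 1L || object@minPositions < 1L)
        msg <- c(msg, "'minTotalReads' and 'minPositions' must be positive")
    if (!object@normalization %in% c("positions", "reads"))
        msg <- c(msg, "'normalization' must be 'positions' or 'reads'")
    if (length(msg)) msg else TRUE
})

#' Create calling parameters
#' @param ratioThreshold allelic-ratio threshold in (0, 0.5].
#' @param minTotalReads per-position depth filter.
#' @param minPositions minimum covered positions for a defined score.
#' @param normalization \code{"positions"} or \code{"reads"}.
#' @return a [CallParams-class].
#' @examples
#' CallParams()                      # defaults: 0.2 / 5 reads / 5 positions
#' CallParams(ratioThreshold = 0.1)
#' @export
CallParams <- function(ratioThreshold = 0.2, minTotalReads = 5L,
                       minPositions = 5L, normalization = "positions") {
    new("CallParams", ratioThreshold = ratioThreshold,
        minTotalReads = as.integer(minTotalReads),
        minPositions = as.integer(minPositions),
        normalization = normalization)
}

setMethod("show", "CallParams", function(object) {
    cat("CallParams: ratio >=", object@ratioThreshold,
        "| depth >=", object@minTotalReads,
        "| >=", object@minPositions, "positions | normalization:",
        object@normalization, "\n")
})

#' Per-cell, per-chromosome bi-allelic score
#'
#' For every (cell, chromosome): the number of positions passing the depth
#' filter (\code{n_covered}), the number of those whose allelic ratio reaches
#' the threshold (\code{n_biallelic}), and the coverage-normalized score used
#' as a marker of the transcriptional activity of the two chromosome copies.
#' Cells with too few covered positions carry \code{defined = FALSE} and an
#' \code{NA} score.
#'
#' @slot summary data.frame: \code{cell_id}, \code{chrom}, \code{n_covered},
#'   \code{n_biallelic}, \code{total_reads}, \code{score}, \code{defined}.
#' @slot params the [CallParams-class] used.
#' @seealso [callBiallelic()], [biallelicScores()]
#' @export
setClass("BiallelicSummary",
    representation(summary = "data.frame", params = "CallParams"))

setValidity("BiallelicSummary", function(object) {
    s <- object@summary
    if (!all(c("cell_id", "chrom", "n_covered", "n_biallelic",
               "score", "defined") %in% colnames(s)))
        return("summary is missing required columns")
    if (nrow(s)) {
        if (any(s$n_biallelic > s$n_covered))
            return("n_biallelic must not exceed n_covered")
        sc <- s$score[s$defined]
        if (length(sc) && (any(sc < 0) || any(sc > 1)))
            return("defined scores must lie in [0,1]")
    }
    TRUE
})

#' @describeIn BiallelicSummary the per-(cell, chromosome) summary table.
#' @param x a BiallelicSummary.
#' @export
biallelicScores <- function(x) x@summary

setMethod("show", "BiallelicSummary", function(object) {
    s <- object@summary
    cat("BiallelicSummary:", nrow(s), "cell x chromosome entries (",
        sum(s$defined), "defined )\n")
    show(object@params)
})

## ---------------------------------------------------------------------------
## CorrelationNull
## ---------------------------------------------------------------------------

#' Empirical gene-null for a target-gene correlation
#'
#' Spearman correlation of a target gene against every gene of a partner set,
#' used to judge whether the correlation with one focal partner stands out of
#' the distribution over partners (the empirical null).
#'
#' @slot targetGene,focalPartner gene ids.
#' @slot rValues named numeric of per-partner Spearman scores (defined only).
#' @slot nExcluded partners dropped for zero variance across cells.
#' @slot focalR Spearman score of target vs focal partner.
#' @slot focalQuantile fraction of partners with r <= focalR, in [0,1].
#' @slot medianR median of the partner correlation scores.
#' @slot nCells cells used after filtering.
#' @seealso [correlationNull()]
#' @export
setClass("CorrelationNull",
    representation(targetGene = "character", focalPartner = "character",
                   rValues = "numeric", nExcluded = "integer",
                   focalR = "numeric", focalQuantile = "numeric",
                   medianR = "numeric", nCells = "integer"))

setValidity("CorrelationNull", function(object) {
    msg <- character()
    r <- object@rValues
    if (length(r) && (any(r < -1 - 1e-12) || any(r > 1 + 1e-12)))
        msg <- c(msg, "correlation scores must lie in [-1,1]")
    if (!is.na(object@focalQuantile) &&
        (object@focalQuantile < 0 || object@focalQuantile > 1))
        msg <- c(msg, "focalQuantile must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationNull", function(object) {
    cat("CorrelationNull:", object@targetGene, "vs",
        length(object@rValues), "partners (", object@nCells, "cells )\n")
    cat(sprintf("  focal partner %s: r = %.3f, quantile = %.3f (median r = %.3f)\n",
                object@focalPartner, object@focalR, object@focalQuantile,
                object@medianR))
    if (object@nExcluded > 0)
        cat("  ", object@nExcluded, "partners excluded (zero variance)\n")
})

## ---------------------------------------------------------------------------
## FishSimConfig and NucleusImage
## ---------------------------------------------------------------------------

#' Configuration for the RNA-FISH nucleus simulator
#'
#' Geometry is isotropic in micrometres on an anisotropic voxel grid. Each
#' fluorescence cloud is a sum of Gaussian puncta whose centres scatter about
#' the cloud centre with standard deviation \code{cloudSpread} - the ground
#' truth behind the measured dispersion. Paired clouds across the two channels
#' are displaced by \code{interChannelOffset}, making inter-channel overlap
#' controllable from complete (0) to none.
#'
#' @slot shape voxels per axis, (z, y, x).
#' @slot voxelSize micrometres per voxel, (z, y, x).
#' @slot nucleusRadius nucleus radius in micrometres; cloud centres are drawn
#'   uniformly inside it.
#' @slot nClouds integer per channel, each in {0, 1, 2}.
#' @slot nPuncta puncta per cloud.
#' @slot punctumSigma isotropic Gaussian sigma of one punctum (micrometres).
#' @slot cloudSpread per-channel sd of puncta positions about the cloud centre
#'   (micrometres); the dispersion ground truth.
#' @slot peakIntensity per-channel peak intensity of one punctum.
#' @slot interChannelOffset micrometres between paired cloud centres.
#' @slot cloudMinSeparation minimum distance between same-channel cloud
#'   centres (micrometres).
#' @slot backgroundMean,backgroundSd Gaussian background noise (clipped at 0).
#' @slot seed integer seed.
#' @seealso [simulateNucleus()], [simulatePopulation()]
#' @export
setClass("FishSimConfig",
    representation(
        shape = "integer", voxelSize = "numeric", nucleusRadius = "numeric",
        nClouds = "integer", nPuncta = "integer", punctumSigma = "numeric",
        cloudSpread = "numeric", peakIntensity = "numeric",
        interChannelOffset = "numeric", cloudMinSeparation = "numeric",
        backgroundMean = "numeric", backgroundSd = "numeric", seed = "integer"))

setValidity("FishSimConfig", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L))
        msg <- c(msg, "'shape' must be 3 positive voxel counts (z,y,x)")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        msg <- c(msg, "'voxelSize' must be 3 positive sizes in um")
    if (length(object@nClouds) != 2L || any(object@nClouds < 0L) ||
        any(object@nClouds > 2L))
        msg <- c(msg, "'nClouds' must give 0, 1 or 2 clouds for each channel")
    if (object@nucleusRadius <= 0)
        msg <- c(msg, "'nucleusRadius' must be positive")
    if (any(object@cloudSpread < 0) || object@punctumSigma <= 0)
        msg <- c(msg, "'cloudSpread' must be >= 0 and 'punctumSigma' > 0")
    if (object@interChannelOffset < 0)
        msg <- c(msg, "'interChannelOffset' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Create a FISH simulation configuration
#'
#' Defaults emulate a confocal stack of one blastomere nucleus with one
#' compact lncRNA cloud per channel, fully overlapping across channels (the
#' co-accumulation regime); raise \code{interChannelOffset} above the cloud
#' extent to simulate spatially separated signals.
#'
#' @param shape,voxelSize image geometry, (z, y, x).
#' @param nucleusRadius nucleus radius (um).
#' @param nClouds clouds per channel, length 2, each in 0:2.
#' @param nPuncta puncta per cloud.
#' @param punctumSigma punctum Gaussian sigma (um).
#' @param cloudSpread per-channel puncta scatter sd (um); recycled to length 2.
#' @param peakIntensity per-channel punctum peak intensity; recycled.
#' @param interChannelOffset distance between paired cloud centres (um).
#' @param cloudMinSeparation minimum same-channel cloud centre distance (um).
#' @param backgroundMean,backgroundSd background noise parameters.
#' @param seed integer seed.
#' @return a [FishSimConfig-class].
#' @examples
#' cfg <- FishSimConfig(seed = 3)
#' img <- simulateNucleus(cfg)
#' @export
FishSimConfig <- function(shape = c(24L, 64L, 64L),
                          voxelSize = c(0.25, 0.1, 0.1),
                          nucleusRadius = 2.2,
                          nClouds = c(1L, 1L),
                          nPuncta = 150L,
                          punctumSigma = 0.25,
                          cloudSpread = 0.5,
                          peakIntensity = 50,
                          interChannelOffset = 0,
                          cloudMinSeparation = 2,
                          backgroundMean = 5,
                          backgroundSd = 2,
                          seed = 1L) {
    new("FishSimConfig",
        shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
        nucleusRadius = nucleusRadius, nClouds = as.integer(nClouds),
        nPuncta = as.integer(nPuncta), punctumSigma = punctumSigma,
        cloudSpread = rep_len(as.numeric(cloudSpread), 2L),
        peakIntensity = rep_len(as.numeric(peakIntensity), 2L),
        interChannelOffset = interChannelOffset,
        cloudMinSeparation = cloudMinSeparation,
        backgroundMean = backgroundMean, backgroundSd = backgroundSd,
        seed = as.integer(seed))
}

setMethod("show", "FishSimConfig", function(object) {
    cat("FishSimConfig:", paste(object@shape, collapse = "x"), "voxels @",
        paste(object@voxelSize, collapse = "x"), "um\n")
    cat("  clouds/channel:", paste(object@nClouds, collapse = ","),
        " spread:", paste(object@cloudSpread, collapse = ","),
        "um  offset:", object@interChannelOffset, "um\n")
})

#' Two-channel 3D nucleus image
#'
#' The unit of every FISH measurement: two same-shape nonnegative 3D intensity
#' arrays (dimension order z, y, x) with voxel dimensions in micrometres, and,
#' for simulated nuclei, the generative ground truth (cloud centres, spreads,
#' inter-channel offset).
#'
#' @slot channels list of two 3D numeric arrays.
#' @slot voxelSize micrometres per voxel, (z, y, x).
#' @slot groundTruth list (possibly empty) of generative parameters.
#' @seealso [simulateNucleus()], [writeNucleusImage()]
#' @export
setClass("NucleusImage",
    representation(channels = "list", voxelSize = "numeric",
                   groundTruth = "list"))

setValidity("NucleusImage", function(object) {
    if (length(object@channels) != 2L)
        return("exactly two channels are required")
    d1 <- dim(object@channels[[1L]]); d2 <- dim(object@channels[[2L]])
    if (length(d1) != 3L || !identical(d1, d2))
        return("channels must be 3D arrays of identical shape")
    if (any(object@voxelSize <= 0) || length(object@voxelSize) != 3L)
        return("voxelSize must be 3 positive values")
    if (any(object@channels[[1L]] < 0) || any(object@channels[[2L]] < 0))
        return("intensities must be nonnegative")
    TRUE
})

#' Construct a NucleusImage
#' @param channels list of two 3D arrays (z, y, x).
#' @param voxelSize micrometres per voxel (z, y, x).
#' @param groundTruth optional list of generative parameters.
#' @return a [NucleusImage-class].
#' @export
NucleusImage <- function(channels, voxelSize, groundTruth = list()) {
    new("NucleusImage", channels = channels,
        voxelSize = as.numeric(voxelSize), groundTruth = groundTruth)
}

#' @describeIn NucleusImage one channel's 3D intensity array.
#' @param x a NucleusImage.
#' @param i channel index (1 or 2).
#' @export
channelArray <- function(x, i) x@channels[[i]]

#' @describeIn NucleusImage voxel dimensions in micrometres (z, y, x).
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn NucleusImage generative ground truth (empty for real images).
#' @export
imageTruth <- function(x) x@groundTruth

setMethod("show", "NucleusImage", function(object) {
    cat("NucleusImage:", paste(dim(object@channels[[1L]]), collapse = "x"),
        "voxels @", paste(object@voxelSize, collapse = "x"), "um\n")
    if (length(object@groundTruth))
        cat("  ground truth: ",
            paste(vapply(object@groundTruth$centers, length, 1L) / 3L,
                  collapse = ","), " cloud(s) per channel\n", sep = "")
})
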