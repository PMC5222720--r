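#' Classify cells as positive or negative for a gene
#'
#' A cell is positive when its expression of \code{gene} strictly exceeds
#' \code{exprThreshold} (so expression exactly at the threshold, including 0
#' under the default, is negative). Used to split late-blastocyst cells into
#' XACT-positive and XACT-negative groups before comparing their X-activity
#' scores.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param gene gene id.
#' @param exprThreshold strict expression cutoff (default 0).
#' @return character vector ("positive"/"negative") named by cell id.
#' @export
classifyFocalStatus <- function(dataset, gene, exprThreshold = 0) {
    stopifnot(is(dataset, "ExpressionDataset"))
    if (!gene %in% rownames(dataset))
        stop("gene '", gene, "' not found in the dataset")
    e <- SummarizedExperiment::assay(dataset, "fpkm")[gene, ]
    stats::setNames(ifelse(e > exprThreshold, "positive", "negative"),
                    colnames(dataset))
}

#' Empirical gene-null for a target-gene correlation
#'
#' Computes the Spearman correlation (average ranks for ties) of a target
#' gene's expression against every gene of a partner set over the filtered
#' cells, and locates one focal partner inside that distribution: the focal
#' quantile is the fraction of partners whose correlation is at most the
#' focal one. This is the test of whether the XIST-XACT correlation stands
#' out of the distribution of XIST correlations with all X-linked genes, as
#' opposed to being a generic consequence of zygotic genome activation.
#' Partners with zero variance across the filtered cells have no defined
#' correlation; they are excluded and counted.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param targetGene the target gene id (e.g. the XIST-like gene).
#' @param partnerSet character vector of partner gene ids (must contain
#'   \code{focalPartner}).
#' @param focalPartner the partner of interest (e.g. the XACT-like gene).
#' @param cellFilter optional logical vector or character vector of cell ids
#'   restricting the cells used (e.g. to post-ZGA stages).
#' @return a [CorrelationNull-class].
#' @export
correlationNull <- function(dataset, targetGene, partnerSet, focalPartner,
                            cellFilter = NULL) {
    stopifnot(is(dataset, "ExpressionDataset"))
    if (!length(partnerSet)) stop("partner set must be nonempty")
    if (!focalPartner %in% partnerSet)
        stop("focal partner must be a member of the partner set")
    miss <- setdiff(c(targetGene, partnerSet), rownames(dataset))
    if (length(miss))
        stop("genes not found: ", paste(miss, collapse = ", "))
    e <- SummarizedExperiment::assay(dataset, "fpkm")
    cells <- colnames(dataset)
    if (!is.null(cellFilter))
        cells <- if (is.logical(cellFilter)) cells[cellFilter]
                 else intersect(cells, cellFilter)
    if (length(cells) < 3L)
        stop("at least 3 cells are required after filtering")
    tgt <- e[targetGene, cells]
    if (sd(tgt) == 0) stop("target gene has zero variance over the cells used")
    prt <- t(e[partnerSet, cells, drop = FALSE])
    sds <- apply(prt, 2L, sd)
    excluded <- names(sds)[sds == 0]
    if (focalPartner %in% excluded)
        stop("focal partner has zero variance over the cells used")
    kept <- setdiff(partnerSet, excluded)
    r <- drop(cor(tgt, prt[, kept, drop = FALSE], method = "spearman"))
    r <- stats::setNames(as.numeric(r), kept)
    focalR <- r[[focalPartner]]
    new("CorrelationNull",
        targetGene = targetGene, focalPartner = focalPartner,
        rValues = r, nExcluded = length(excluded),
        focalR = focalR, focalQuantile = mean(r <= focalR),
        medianR = median(r), nCells = length(cells))
}

#' Per-gene mono-/bi-allelic classification with condition comparison
#'
#' Pools allele counts per (gene, position) across the cells of each
#' condition, calls each pooled position informative when its depth passes
#' \code{params@minTotalReads} and bi-allelic when its pooled allelic ratio
#' reaches \code{params@ratioThreshold}, then classifies each gene:
#' \code{uninformative} below \code{perGeneMinPositions} informative
#' positions, \code{biallelic} with at least \code{minBiallelicPositions}
#' bi-allelic positions, \code{monoallelic} otherwise. With a two-level
#' \code{conditions} vector, the mono/bi gene counts of the two conditions
#' are compared by a two-sided Fisher's exact test on the 2x2 table
#' (uninformative genes excluded).
#'
#' @param table an [AlleleCountTable-class].
#' @param params a [CallParams-class] (ratio and depth filters reused).
#' @param conditions NULL, or a condition label per cell, named by cell id,
#'   with exactly two distinct values.
#' @param perGeneMinPositions minimum informative positions per gene.
#' @param minBiallelicPositions bi-allelic positions required for a
#'   bi-allelic gene call.
#' @return with conditions: list(\code{calls} data.frame, \code{table} 2x2
#'   matrix (rows conditions, cols mono/bi), \code{p_value}); without:
#'   the calls data.frame alone.
#' @export
geneAllelicCalls <- function(table, params = CallParams(), conditions = NULL,
                             perGeneMinPositions = 2L,
                             minBiallelicPositions = 1L) {
    stopifnot(is(table, "AlleleCountTable"))
    r <- alleleRecords(table)

    callsFor <- function(rec) {
        dt <- data.table::as.data.table(rec)
        pooled <- dt[, .(ref = sum(ref_count), alt = sum(alt_count)),
                     by = .(gene, chrom, pos)]
        pooled[, tot := ref + alt]
        pooled[, informative := tot >= params@minTotalReads]
        pooled[, bi := informative & pmin(ref, alt) / tot >= params@ratioThreshold]
        g <- pooled[, .(n_informative = sum(informative),
                        n_biallelic = sum(bi)), by = gene]
        g[, call := ifelse(n_informative < perGeneMinPositions, "uninformative",
                    ifelse(n_biallelic >= minBiallelicPositions,
                           "biallelic", "monoallelic"))]
        data.table::setorder(g, gene)
        as.data.frame(g)
    }

    if (is.null(conditions))
        return(callsFor(r))

    lv <- sort(unique(as.character(conditions)))
    if (length(lv) != 2L) stop("exactly two conditions are required")
    if (is.null(names(conditions)))
        stop("'conditions' must be named by cell id")
    out <- lapply(lv, function(cond) {
        cells <- names(conditions)[conditions == cond]
        calls <- callsFor(r[r$cell_id %in% cells, , drop = FALSE])
        informative <- calls[calls$call != "uninformative", , drop = FALSE]
        if (!nrow(informative))
            stop("condition '", cond, "' has no informative genes")
        cbind(condition = cond, calls)
    })
    calls <- do.call(rbind, out)
    inf <- calls[calls$call != "uninformative", , drop = FALSE]
    tab <- vapply(lv, function(cond) c(
        monoallelic = sum(inf$condition == cond & inf$call == "monoallelic"),
        biallelic = sum(inf$condition == cond & inf$call == "biallelic")),
        c(monoallelic = 0, biallelic = 0))
    tab <- t(tab)
    p <- stats::fisher.test(tab)$p.value
    list(calls = calls, table = tab, p_value = p)
}
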