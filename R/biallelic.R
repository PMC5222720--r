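#' @import data.table
NULL

#' Call bi-allelic positions and score per-cell chromosome activity
#'
#' A position is covered when \code{ref_count + alt_count >=
#' minTotalReads}; a covered position is bi-allelic when its minor-allele
#' ratio is at least \code{ratioThreshold} (boundary inclusive). Per (cell,
#' chromosome) the coverage-normalized score is the bi-allelic count divided
#' by the covered-position count (or by total covered read depth under the
#' \code{"reads"} normalization). Entries with fewer than \code{minPositions}
#' covered positions are flagged \code{defined = FALSE} with an \code{NA}
#' score - never silently zero. An excess of bi-allelic X positions marks two
#' transcriptionally active X chromosomes; its loss marks the initiation of
#' X inactivation.
#'
#' @param table an [AlleleCountTable-class].
#' @param params a [CallParams-class].
#' @return a [BiallelicSummary-class], ordered by cell then chromosome.
#' @examples
#' tab <- AlleleCountTable(data.frame(
#'     cell_id = "c1", chrom = "X", pos = 1:3, gene = "g",
#'     ref_count = c(10L, 19L, 8L), alt_count = c(10L, 1L, 2L)))
#' biallelicScores(callBiallelic(tab, CallParams(0.2, 5, 1)))
#' @export
callBiallelic <- function(table, params = CallParams()) {
    stopifnot(is(table, "AlleleCountTable"))
    validObject(params)
    r <- alleleRecords(table)
    if (!nrow(r)) {
        empty <- data.frame(cell_id = character(), chrom = character(),
                            n_covered = integer(), n_biallelic = integer(),
                            total_reads = integer(), score = numeric(),
                            defined = logical())
        return(new("BiallelicSummary", summary = empty, params = params))
    }
    dt <- data.table::as.data.table(r)
    dt[, tot := ref_count + alt_count]
    dt[, covered := tot >= params@minTotalReads]
    dt[, ratio := ifelse(tot > 0, pmin(ref_count, alt_count) / tot, NA_real_)]
    dt[, bi := covered & ratio >= params@ratioThreshold]
    agg <- dt[, .(n_covered = sum(covered), n_biallelic = sum(bi),
                  total_reads = sum(tot[covered])),
              by = .(cell_id, chrom)]
    agg[, defined := n_covered >= params@minPositions]
    if (params@normalization == "positions") {
        agg[, score := ifelse(defined, n_biallelic / n_covered, NA_real_)]
    } else {
        agg[, score := ifelse(defined & total_reads > 0,
                              n_biallelic / total_reads, NA_real_)]
    }
    data.table::setorder(agg, cell_id, chrom)
    out <- as.data.frame(agg[, .(cell_id, chrom, n_covered, n_biallelic,
                                 total_reads, score, defined)])
    new("BiallelicSummary", summary = out, params = params)
}

#' Sensitivity of bi-allelic calls to the allelic-ratio threshold
#'
#' Reruns [callBiallelic()] over a ladder of ratio thresholds. Because the
#' coverage filter does not depend on the ratio, \code{n_covered} is constant
#' across thresholds while \code{n_biallelic} is non-increasing, for every
#' cell and chromosome.
#'
#' @param table an [AlleleCountTable-class].
#' @param thresholds numeric vector of ratio thresholds, each in (0, 0.5].
#' @param params baseline [CallParams-class] (its ratioThreshold is ignored).
#' @return data.frame with a \code{threshold} column prepended to the usual
#'   summary columns.
#' @export
thresholdSweep <- function(table, thresholds, params = CallParams()) {
    if (any(thresholds <= 0 | thresholds > 0.5))
        stop("all thresholds must lie in (0, 0.5]")
    out <- lapply(thresholds, function(th) {
        p <- CallParams(ratioThreshold = th,
                        minTotalReads = params@minTotalReads,
                        minPositions = params@minPositions,
                        normalization = params@normalization)
        cbind(threshold = th, biallelicScores(callBiallelic(table, p)))
    })
    do.call(rbind, out)
}
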