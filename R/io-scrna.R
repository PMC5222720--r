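#' @importFrom utils read.delim write.table tail head combn
NULL

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a dataset bundle to a directory
#'
#' Writes an expression matrix (genes x cells TSV with a header row of cell
#' ids, or an MTX triplet with gene/cell name files), gene and cell metadata
#' TSVs, the allele count table TSV (columns \code{chrom, pos, gene, cell_id,
#' ref_count, alt_count}), the latent ground-truth TSV when present, and a
#' JSON sidecar carrying the stage order and the matrix format. The round
#' trip through [readScrnaDataset()] is lossless.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param table an [AlleleCountTable-class] (or NULL to skip).
#' @param path output directory (created if needed).
#' @param format \code{"tsv"} (dense, full precision) or \code{"mtx"}.
#' @return \code{path}, invisibly.
#' @export
writeScrnaDataset <- function(dataset, table, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    m <- SummarizedExperiment::assay(dataset, "fpkm")

    if (format == "tsv") {
        em <- data.frame(gene_id = rownames(m), apply(m, 2, fmtNum),
                         check.names = FALSE, stringsAsFactors = FALSE)
        colnames(em) <- c("gene_id", colnames(m))
        write.table(em, file.path(path, "expression.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    } else {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                        file.path(path, "expression.mtx"))
        writeLines(rownames(m), file.path(path, "genes.txt"))
        writeLines(colnames(m), file.path(path, "cells.txt"))
    }

    rd <- as.data.frame(SummarizedExperiment::rowData(dataset))
    write.table(cbind(gene_id = rownames(rd), rd),
                file.path(path, "gene_meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(dataset))
    write.table(cd[, c("cell_id", "embryo_id", "stage", "sex", "lineage")],
                file.path(path, "cell_meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(table)) {
        r <- alleleRecords(table)
        write.table(r[, c("chrom", "pos", "gene", "cell_id",
                          "ref_count", "alt_count")],
                    file.path(path, "allele_counts.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        tr <- alleleTruth(table)
        if (nrow(tr))
            write.table(tr, file.path(path, "allele_truth.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
        list(stages = stageLevels(dataset), matrix_format = format),
        file.path(path, "dataset.json"), auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' Read a dataset bundle written by [writeScrnaDataset()]
#'
#' @param path directory containing the bundle.
#' @return list with elements \code{dataset} ([ExpressionDataset-class]) and
#'   \code{table} ([AlleleCountTable-class], NULL when absent).
#' @export
readScrnaDataset <- function(path) {
    meta <- jsonlite::read_json(file.path(path, "dataset.json"),
                                simplifyVector = TRUE)
    if (identical(meta$matrix_format, "mtx")) {
        m <- as.matrix(Matrix::readMM(file.path(path, "expression.mtx")))
        rownames(m) <- readLines(file.path(path, "genes.txt"))
        colnames(m) <- readLines(file.path(path, "cells.txt"))
    } else {
        em <- read.delim(file.path(path, "expression.tsv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
        if (colnames(em)[1L] != "gene_id")
            stop("malformed expression header: first column must be 'gene_id'")
        m <- as.matrix(em[, -1L, drop = FALSE])
        rownames(m) <- em$gene_id
    }
    rd <- read.delim(file.path(path, "gene_meta.tsv"),
                     stringsAsFactors = FALSE)
    rownames(rd) <- rd$gene_id
    rd$gene_id <- NULL
    cd <- read.delim(file.path(path, "cell_meta.tsv"),
                     colClasses = "character")
    dataset <- ExpressionDataset(t(m), rd, cd, stages = meta$stages)

    table <- NULL
    acPath <- file.path(path, "allele_counts.tsv")
    if (file.exists(acPath)) {
        table <- readAlleleCounts(acPath)
        trPath <- file.path(path, "allele_truth.tsv")
        if (file.exists(trPath)) {
            tr <- read.delim(trPath, stringsAsFactors = FALSE)
            tr$true_biallelic <- as.logical(tr$true_biallelic)
            table <- AlleleCountTable(alleleRecords(table), truth = tr)
        }
    }
    list(dataset = dataset, table = table)
}

#' Read an allele count table from TSV
#'
#' Expects the columns \code{chrom, pos, gene, cell_id, ref_count, alt_count}
#' (any order). Validation failures - a malformed header, non-integer counts,
#' duplicated (cell, chromosome, position) keys - raise a parse error naming
#' the offending line (1-based, counting the header as line 1). An empty body
#' with a valid header yields an empty table.
#'
#' @param path TSV file.
#' @return an [AlleleCountTable-class] (without ground truth).
#' @export
readAlleleCounts <- function(path) {
    need <- c("chrom", "pos", "gene", "cell_id", "ref_count", "alt_count")
    raw <- read.delim(path, colClasses = "character",
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(need %in% colnames(raw)))
        stop("malformed header in '", path, "': need columns ",
             paste(setdiff(need, colnames(raw)), collapse = ", "))
    if (!nrow(raw))
        return(AlleleCountTable(data.frame(
            cell_id = character(), chrom = character(), pos = integer(),
            gene = character(), ref_count = integer(), alt_count = integer())))
    intOk <- function(v) grepl("^[0-9]+$", v)
    for (col in c("pos", "ref_count", "alt_count")) {
        bad <- which(!intOk(raw[[col]]))
        if (length(bad))
            stop("parse error at line ", bad[1L] + 1L, " of '", path,
                 "': column '", col, "' value '", raw[[col]][bad[1L]],
                 "' is not a nonnegative integer")
    }
    dup <- which(duplicated(raw[, c("cell_id", "chrom", "pos")]))
    if (length(dup))
        stop("parse error at line ", dup[1L] + 1L, " of '", path,
             "': duplicate (cell_id, chrom, pos) record")
    AlleleCountTable(data.frame(
        cell_id = raw$cell_id, chrom = raw$chrom, pos = as.integer(raw$pos),
        gene = raw$gene, ref_count = as.integer(raw$ref_count),
        alt_count = as.integer(raw$alt_count), stringsAsFactors = FALSE))
}

#' Import allele counts from a VCF with per-sample AD fields
#'
#' Each sample column becomes a cell; the AD field's first two values are
#' taken as reference and alternative read counts. Gene annotation is read
#' from an INFO key (default \code{GENE}) when present, otherwise left empty.
#' Positions without an AD entry for a sample are skipped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param geneInfoKey INFO key holding the gene name.
#' @return an [AlleleCountTable-class].
#' @export
readAlleleCountsVCF <- function(path, geneInfoKey = "GENE") {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("package 'vcfR' is required for VCF import")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    gene <- rep("", nrow(ad))
    info <- fix[, "INFO"]
    hit <- regmatches(info, regexpr(paste0(geneInfoKey, "=[^;]+"), info))
    has <- grepl(paste0(geneInfoKey, "="), info)
    gene[has] <- sub(paste0(geneInfoKey, "="), "", hit)

    out <- list()
    for (s in colnames(ad)) {
        keep <- !is.na(ad[, s]) & ad[, s] != "."
        if (!any(keep)) next
        parts <- strsplit(ad[keep, s], ",", fixed = TRUE)
        out[[s]] <- data.frame(
            cell_id = s, chrom = as.character(fix[keep, "CHROM"]),
            pos = as.integer(fix[keep, "POS"]), gene = gene[keep],
            ref_count = as.integer(vapply(parts, `[`, "", 1L)),
            alt_count = as.integer(vapply(parts, function(p)
                if (length(p) >= 2L) p[2L] else "0", "")),
            stringsAsFactors = FALSE)
    }
    AlleleCountTable(do.call(rbind, out))
}
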