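## End-to-end runs: simulate -> analyze -> report, deterministic under
## config + seed. Logs are step-numbered (no wall-clock timestamps) so two
## runs with identical configuration are byte-identical.

s4ToList <- function(x) {
    out <- lapply(methods::slotNames(x), function(s) methods::slot(x, s))
    names(out) <- methods::slotNames(x)
    out
}

configHash <- function(x) {
    if (isVirtualClass(class(x)) || is(x, "ScrnaSimConfig") ||
        is(x, "FishSimConfig") || is(x, "CallParams")) x <- s4ToList(x)
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(deparse(x, control = c("keepNA", "keepInteger")), tmp)
    unname(tools::md5sum(tmp))
}

writeStamped <- function(df, path, seed, hash) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# seed=%d config=%s", seed, hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

withStage <- function(stage, hash, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "' failed [config ", hash, "]: ",
             conditionMessage(e), call. = FALSE))
}

#' Run the sequencing arm end to end
#'
#' Simulates an expression matrix and allele counts, scores per-cell
#' bi-allelic X activity, tests the stage trend (female X scores), compares
#' scores between cells positive and negative for the XACT-like focal gene
#' at the final stage, places the focal-pair correlation inside the gene
#' null, and classifies genes mono-/bi-allelic at the first versus last
#' stage. Writes the data bundle, per-analysis TSVs, a machine-readable JSON
#' summary and a step log into \code{outDir}. Fully deterministic under
#' (config, params).
#'
#' @param config a [ScrnaSimConfig-class].
#' @param outDir output directory.
#' @param params a [CallParams-class].
#' @return the summary list, invisibly (also in \code{summary.json}).
#' @export
runScrnaPipeline <- function(config, outDir, params = CallParams()) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    hash <- configHash(config)
    seed <- config@seed
    log <- character()
    note <- function(msg) log <<- c(log, sprintf("[%02d] %s", length(log) + 1L, msg))

    note("simulate expression + allele counts")
    dataset <- withStage("simulate", hash, simulateExpression(config))
    table <- withStage("simulate", hash, simulateAlleleCounts(dataset, config))
    writeScrnaDataset(dataset, table, file.path(outDir, "data"))

    note("bi-allelic scoring")
    bs <- withStage("score", hash, callBiallelic(table, params))
    writeStamped(biallelicScores(bs), file.path(outDir, "biallelic_summary.tsv"),
                 seed, hash)

    cd <- as.data.frame(SummarizedExperiment::colData(dataset))
    s <- biallelicScores(bs)
    sx <- s[s$chrom == "X", ]
    sx <- merge(sx, cd[, c("cell_id", "stage", "sex")], by = "cell_id")
    fem <- sx[sx$sex == "F", ]
    stages <- stageLevels(dataset)

    note("stage trend of female X scores")
    trend <- withStage("trend", hash,
        stageTrend(fem$score, fem$stage, stages))
    direction <- if (is.na(trend$trend_r)) "flat"
                 else if (trend$trend_r <= -0.2) "decreasing"
                 else if (trend$trend_r >= 0.2) "increasing" else "flat"
    terminal <- withStage("trend", hash, {
        a <- fem$score[fem$stage == utils::head(trend$perStage$stage, 1L)]
        b <- fem$score[fem$stage == utils::tail(trend$perStage$stage, 1L)]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) >= 2L && length(b) >= 2L) rankSumTest(a, b)$p_value
        else NA_real_
    })
    writeStamped(trend$perStage, file.path(outDir, "stage_trend.tsv"),
                 seed, hash)
    writeStamped(trend$adjacent, file.path(outDir, "stage_pairs.tsv"),
                 seed, hash)

    note("focal-status comparison at the final stage")
    fg <- focalGenes(dataset)
    lastStage <- utils::tail(stages, 1L)
    lastFem <- cd$cell_id[cd$stage == lastStage & cd$sex == "F"]
    focalCmp <- NULL
    if (length(lastFem) >= 4L) {
        status <- classifyFocalStatus(dataset, fg[["focal2"]])[lastFem]
        sc <- fem$score[match(lastFem, fem$cell_id)]
        ok <- !is.na(sc)
        if (length(unique(status[ok])) == 2L &&
            min(table(status[ok])) >= 2L)
            focalCmp <- compareScoreGroups(sc[ok], status[ok])
    }
    if (is.null(focalCmp)) note("  (skipped: not enough cells per status)")

    note("focal-pair correlation against the X-linked gene null")
    post <- cd$stage %in% stages[seq(match(config@zgaStage, stages),
                                     length(stages))]
    rd <- as.data.frame(SummarizedExperiment::rowData(dataset))
    partners <- setdiff(rownames(rd)[rd$chrom == "X"], fg[["focal1"]])
    cn <- withStage("corrnull", hash,
        correlationNull(dataset, fg[["focal1"]], partners, fg[["focal2"]],
                        cellFilter = cd$cell_id[post]))
    writeStamped(data.frame(partner = names(cn@rValues), r = cn@rValues),
                 file.path(outDir, "correlation_null.tsv"), seed, hash)

    note("per-gene allelic calls, first vs last stage")
    firstStage <- trend$perStage$stage[1L]
    conds <- stats::setNames(cd$stage, cd$cell_id)
    conds <- conds[conds %in% c(firstStage, lastStage)]
    gc <- withStage("genecalls", hash,
        geneAllelicCalls(table, params, conditions = conds))
    writeStamped(gc$calls, file.path(outDir, "gene_calls.tsv"), seed, hash)

    summary <- list(
        seed = seed, config_hash = hash,
        n_cells = nrow(cd), n_records = nrow(table),
        trend = list(direction = direction, spearman_r = trend$trend_r,
                     terminal_p = terminal,
                     stage_medians = stats::setNames(
                         trend$perStage$median, trend$perStage$stage)),
        focal_comparison = if (is.null(focalCmp)) NULL else list(
            p_value = focalCmp$p_value,
            group_medians = as.list(focalCmp$group_medians),
            n = as.list(focalCmp$n)),
        correlation_null = list(focal_r = cn@focalR,
                                focal_quantile = cn@focalQuantile,
                                median_r = cn@medianR,
                                n_partners = length(cn@rValues)),
        gene_calls = list(table = as.data.frame(gc$table),
                          fisher_p = gc$p_value))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    note("done")
    writeLines(log, file.path(outDir, "run.log"))
    invisible(summary)
}

#' Run the imaging arm end to end
#'
#' Simulates one nucleus population per group (groups override fields of the
#' template configuration - e.g. distinct \code{cloudSpread} values),
#' measures every nucleus (per-channel Otsu threshold, cloud segmentation,
#' volume, dispersion), computes per-nucleus co-localization, tabulates cloud
#' count patterns per group, and compares the first two groups: Wilcoxon
#' rank-sum on channel-1 cloud dispersion and volume, Fisher's exact test on
#' the pattern table. Writes TSVs, a JSON summary and a step log; byte
#' deterministic under the configuration.
#'
#' @param config a [FishSimConfig-class] template.
#' @param outDir output directory.
#' @param groups named list; each element a named list of FishSimConfig
#'   slot overrides for that group.
#' @param nNuclei nuclei per group.
#' @return the summary list, invisibly.
#' @export
runFishPipeline <- function(config, outDir,
                            groups = list(compact = list(cloudSpread = 0.5),
                                          dispersed = list(cloudSpread = 2.0)),
                            nNuclei = 12L) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    hash <- configHash(config)
    seed <- config@seed
    log <- character()
    note <- function(msg) log <<- c(log, sprintf("[%02d] %s", length(log) + 1L, msg))

    set.seed(seed)
    groupSeeds <- sample.int(.Machine$integer.max - 1L, length(groups))
    note(sprintf("simulate %d nuclei for %d group(s)", nNuclei, length(groups)))
    pops <- withStage("simulate", hash, lapply(seq_along(groups), function(g) {
        cfg <- config
        for (nm in names(groups[[g]])) {
            v <- groups[[g]][[nm]]
            if (nm %in% c("cloudSpread", "peakIntensity"))
                v <- rep_len(as.numeric(v), 2L)
            if (nm %in% c("nClouds", "nPuncta", "shape"))
                v <- as.integer(v)
            methods::slot(cfg, nm) <- v
        }
        cfg@seed <- groupSeeds[g]
        simulatePopulation(cfg, nNuclei,
                           stats::setNames(1, names(groups)[g]))
    }))
    nuclei <- do.call(c, lapply(pops, `[[`, "nuclei"))
    labels <- do.call(rbind, lapply(pops, `[[`, "labels"))

    note("measure clouds (threshold, volume, dispersion)")
    perCloud <- list(); perNuc <- list()
    withStage("measure", hash, for (i in seq_along(nuclei)) {
        img <- nuclei[[i]]
        for (ch in 1:2) {
            arr <- channelArray(img, ch)
            thr <- computeThreshold(arr)
            cl <- segmentClouds(arr, thr, voxelSize(img))
            if (nrow(cl))
                perCloud[[length(perCloud) + 1L]] <-
                    cbind(nucleus_id = labels$nucleus_id[i],
                          group = labels$group[i], channel = ch,
                          threshold = thr, cl)
            perNuc[[length(perNuc) + 1L]] <- data.frame(
                nucleus_id = labels$nucleus_id[i],
                group = labels$group[i], channel = ch,
                n_clouds = nrow(cl),
                total_volume_um3 = sum(cl$volume_um3),
                signal_dispersion = if (nrow(cl))
                    cloudDispersion(arr, sort(unlist(attr(cl, "masks"))),
                                    voxelSize(img)) else NA_real_)
        }
    })
    meas <- do.call(rbind, perCloud)
    nuc <- do.call(rbind, perNuc)
    writeStamped(meas, file.path(outDir, "measurements.tsv"), seed, hash)
    writeStamped(nuc, file.path(outDir, "nucleus_measurements.tsv"), seed, hash)

    note("per-nucleus co-localization")
    coloc <- withStage("coloc", hash, colocalizeNuclei(nuclei))
    writeStamped(coloc$perNucleus, file.path(outDir, "coloc.tsv"), seed, hash)

    note("cloud-count patterns per group")
    pat <- withStage("patterns", hash,
        countCloudPatterns(nuclei, labels$group))
    writeStamped(pat$perNucleus, file.path(outDir, "patterns.tsv"), seed, hash)

    gl <- names(groups)
    cmp <- NULL
    if (length(gl) >= 2L) {
        note(sprintf("compare groups '%s' vs '%s'", gl[1L], gl[2L]))
        d1 <- nuc$signal_dispersion[nuc$group == gl[1L] & nuc$channel == 1L]
        d2 <- nuc$signal_dispersion[nuc$group == gl[2L] & nuc$channel == 1L]
        v1 <- nuc$total_volume_um3[nuc$group == gl[1L] & nuc$channel == 2L]
        v2 <- nuc$total_volume_um3[nuc$group == gl[2L] & nuc$channel == 2L]
        cmp <- withStage("compare", hash, list(
            dispersion = compareMeasurements(d1, d2),
            volume = compareMeasurements(v1, v2),
            patterns = comparePatterns(pat$counts[[1L]][gl[1L], ],
                                       pat$counts[[1L]][gl[2L], ])))
    }

    summary <- list(
        seed = seed, config_hash = hash,
        n_nuclei = length(nuclei), groups = gl,
        median_coloc_r = coloc$median_r,
        group_median_dispersion = stats::setNames(lapply(gl, function(g)
            median(nuc$signal_dispersion[nuc$group == g & nuc$channel == 1L],
                   na.rm = TRUE)), gl),
        group_median_volume = stats::setNames(lapply(gl, function(g)
            median(nuc$total_volume_um3[nuc$group == g & nuc$channel == 2L],
                   na.rm = TRUE)), gl),
        comparisons = if (is.null(cmp)) NULL else list(
            dispersion_p = cmp$dispersion$p_value,
            dispersion_medians = as.list(cmp$dispersion$group_medians),
            volume_p = cmp$volume$p_value,
            pattern_fisher_p = cmp$patterns$p_value))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    note("done")
    writeLines(log, file.path(outDir, "run.log"))
    invisible(summary)
}

#' Read a run configuration from YAML
#'
#' Sections: \code{seed}; \code{scrna} (\code{enabled} plus any
#' [ScrnaSimConfig()] arguments and a \code{callParams} block); \code{fish}
#' (\code{enabled} plus [FishSimConfig()] arguments, a \code{groups} block of
#' per-group overrides and \code{nNuclei}).
#'
#' @param path YAML file.
#' @return the parsed configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Run both arms from a run configuration
#'
#' Executes the sequencing and/or imaging pipelines according to the
#' \code{enabled} flags of the configuration (see [readRunConfig()]),
#' writing each arm into its own subdirectory of \code{outDir}.
#'
#' @param runConfig list from [readRunConfig()] (or constructed in code).
#' @param outDir output directory.
#' @return list with the per-arm summaries (absent arms omitted).
#' @export
runPipeline <- function(runConfig, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- if (is.null(runConfig$seed)) 1L else as.integer(runConfig$seed)
    out <- list()
    sc <- runConfig$scrna
    if (!is.null(sc) && isTRUE(sc$enabled)) {
        cp <- do.call(CallParams, if (is.null(sc$callParams)) list()
                      else sc$callParams)
        args <- sc[setdiff(names(sc), c("enabled", "callParams"))]
        for (nm in intersect(names(args),
                             c("biallelicFractionByStage", "nPositionsPerChrom",
                               "nGenesPerChrom", "lineageProbs",
                               "cellsPerEmbryo")))
            args[[nm]] <- unlist(args[[nm]])
        cfg <- do.call(ScrnaSimConfig, c(args, list(seed = seed)))
        out$scrna <- runScrnaPipeline(cfg, file.path(outDir, "scrna"), cp)
    }
    fi <- runConfig$fish
    if (!is.null(fi) && isTRUE(fi$enabled)) {
        grp <- fi$groups
        nn <- if (is.null(fi$nNuclei)) 12L else as.integer(fi$nNuclei)
        args <- fi[setdiff(names(fi), c("enabled", "groups", "nNuclei"))]
        for (nm in intersect(names(args),
                             c("shape", "voxelSize", "nClouds", "cloudSpread",
                               "peakIntensity")))
            args[[nm]] <- unlist(args[[nm]])
        cfg <- do.call(FishSimConfig, c(args, list(seed = seed)))
        out$fish <- if (is.null(grp))
            runFishPipeline(cfg, file.path(outDir, "fish"), nNuclei = nn)
        else runFishPipeline(cfg, file.path(outDir, "fish"),
                             groups = lapply(grp, as.list), nNuclei = nn)
    }
    invisible(out)
}
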