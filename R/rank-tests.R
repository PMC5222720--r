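## Two-sample rank tests and contingency comparisons shared by the
## sequencing and imaging arms.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' For combined sample sizes up to \code{exactMax} the p-value is computed by
#' full enumeration of all assignments of the pooled (average) ranks to the
#' first group, which remains exact in the presence of ties; the two-sided
#' p-value is \code{min(1, 2 * min(P(W <= w), P(W >= w)))}. For larger
#' samples a tie-corrected normal approximation with continuity correction is
#' used (matching the standard large-sample treatment).
#'
#' @param x,y numeric samples.
#' @param exactMax largest combined size for the enumeration branch.
#' @return list: \code{statistic} (Mann-Whitney U of the first sample),
#'   \code{p_value}, \code{method} ("exact" or "normal"), \code{medians}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p_value   # 0.1 by enumeration
#' @export
rankSumTest <- function(x, y, exactMax = 20L) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    if (n1 < 1L || n2 < 1L) stop("both samples must be nonempty")
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    U <- W - n1 * (n1 + 1) / 2
    eps <- 1e-9
    if (n <= exactMax) {
        allW <- utils::combn(n, n1, FUN = function(i) sum(r[i]))
        p <- min(1, 2 * min(mean(allW <= W + eps), mean(allW >= W - eps)))
        method <- "exact"
    } else {
        mu <- n1 * n2 / 2
        tie <- table(r)
        sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
        z <- U - mu
        z <- (z - sign(z) * 0.5) / sqrt(sigma2)
        p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
        method <- "normal"
    }
    list(statistic = U, p_value = p, method = method,
         medians = c(median(x), median(y)))
}

#' Compare bi-allelic scores (or any measurement) between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the defined values of two groups, as
#' used to contrast X-activity scores between XACT-positive and -negative
#' cells, or FISH volumes/dispersions between conditions. \code{NA} values
#' are dropped; each group must retain at least two values.
#'
#' @param scores numeric vector (may contain NA).
#' @param groups vector of exactly two distinct labels, aligned with scores.
#' @return list: \code{statistic}, \code{p_value}, \code{method},
#'   \code{group_medians} (named), \code{n} (named group sizes).
#' @export
compareScoreGroups <- function(scores, groups) {
    keep <- !is.na(scores)
    scores <- scores[keep]; groups <- as.character(groups[keep])
    lv <- sort(unique(groups))
    if (length(lv) != 2L)
        stop("exactly two groups are required, got: ",
             paste(lv, collapse = ", "))
    a <- scores[groups == lv[1L]]; b <- scores[groups == lv[2L]]
    if (length(a) < 2L || length(b) < 2L)
        stop("group '", lv[which.min(c(length(a), length(b)))],
             "' has fewer than 2 defined scores")
    t <- rankSumTest(a, b)
    list(statistic = t$statistic, p_value = t$p_value, method = t$method,
         group_medians = stats::setNames(t$medians, lv),
         n = stats::setNames(c(length(a), length(b)), lv))
}

#' @rdname compareScoreGroups
#' @param valuesA,valuesB the two measurement samples directly.
#' @export
compareMeasurements <- function(valuesA, valuesB) {
    compareScoreGroups(c(valuesA, valuesB),
                       rep(c("A", "B"), c(length(valuesA), length(valuesB))))
}

#' Per-stage score summary with adjacent-stage tests and trend
#'
#' Summarizes defined scores per developmental stage (n, median, quartiles),
#' tests each pair of adjacent non-empty stages with the two-sided Wilcoxon
#' rank-sum test, and reports the Spearman correlation of score versus stage
#' rank as the overall trend. Stages with no defined scores are skipped with
#' a warning and listed in the output. No multiple-testing correction is
#' applied; p-values are reported raw.
#'
#' @param scores numeric vector of scores (NA allowed).
#' @param stages stage label per score.
#' @param stageOrder ordered vector of stage labels.
#' @return list: \code{perStage} (data.frame), \code{adjacent} (data.frame of
#'   stage pairs with statistic and p), \code{trend_r}, \code{skipped}.
#' @export
stageTrend <- function(scores, stages, stageOrder) {
    keep <- !is.na(scores) & stages %in% stageOrder
    scores <- scores[keep]; stages <- as.character(stages[keep])
    present <- stageOrder[stageOrder %in% stages]
    skipped <- setdiff(stageOrder, present)
    if (length(skipped))
        warning("stages with no defined scores skipped: ",
                paste(skipped, collapse = ", "))
    if (length(present) < 2L)
        stop("at least two stages with defined scores are required")
    perStage <- do.call(rbind, lapply(present, function(s) {
        v <- scores[stages == s]
        data.frame(stage = s, n = length(v), median = median(v),
                   q1 = unname(quantile(v, 0.25)),
                   q3 = unname(quantile(v, 0.75)))
    }))
    adjacent <- do.call(rbind, lapply(seq_len(length(present) - 1L), function(i) {
        a <- scores[stages == present[i]]
        b <- scores[stages == present[i + 1L]]
        if (length(a) >= 2L && length(b) >= 2L) {
            t <- rankSumTest(a, b)
            data.frame(stage_a = present[i], stage_b = present[i + 1L],
                       statistic = t$statistic, p_value = t$p_value)
        } else {
            data.frame(stage_a = present[i], stage_b = present[i + 1L],
                       statistic = NA_real_, p_value = NA_real_)
        }
    }))
    trend <- suppressWarnings(
        cor(scores, match(stages, stageOrder), method = "spearman"))
    list(perStage = perStage, adjacent = adjacent, trend_r = trend,
         skipped = skipped)
}

#' Compare pattern-category counts between two groups
#'
#' Builds the groups x categories contingency table. A table with a zero
#' margin yields p = 1 with a warning. A 2x2 table is tested with the exact
#' two-sided Fisher test (hypergeometric); larger tables use the exact
#' network algorithm when the grand total is at most \code{exactTotalMax},
#' otherwise a chi-square test with a warning.
#'
#' @param countsA,countsB named nonnegative integer vectors over matching
#'   categories.
#' @param exactTotalMax largest grand total for exact r x c testing.
#' @return list: \code{p_value}, \code{method}, \code{table}.
#' @examples
#' comparePatterns(c(a = 5, b = 0), c(a = 0, b = 5))$p_value  # 2/252
#' @export
comparePatterns <- function(countsA, countsB, exactTotalMax = 30L) {
    if (!identical(sort(names(countsA)), sort(names(countsB))))
        stop("the two groups must share the same pattern categories")
    countsB <- countsB[names(countsA)]
    tab <- rbind(A = countsA, B = countsB)
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be nonnegative integers")
    tab <- tab[, colSums(tab) > 0, drop = FALSE]   # unobserved categories
    if (ncol(tab) < 2L || any(rowSums(tab) == 0)) {
        warning("contingency table has a zero margin; p = 1")
        return(list(p_value = 1, method = "degenerate", table = tab))
    }
    if (all(dim(tab) == 2L)) {
        p <- stats::fisher.test(tab)$p.value
        method <- "fisher"
    } else if (sum(tab) <= exactTotalMax) {
        p <- stats::fisher.test(tab)$p.value
        method <- "fisher"
    } else {
        warning("table too large for exact enumeration; using chi-square")
        p <- suppressWarnings(stats::chisq.test(tab)$p.value)
        method <- "chisq"
    }
    list(p_value = p, method = method, table = tab)
}
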