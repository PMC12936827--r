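#' @importFrom stats cor wilcox.test t.test
NULL

# Spearman rho with average-rank ties and the t-approximation p on n-2 df
.spearmanRecord <- function(xv, yv) {
    ok <- !is.na(xv) & !is.na(yv)
    n <- sum(ok)
    if (n < 3L || length(unique(xv[ok])) < 2L || length(unique(yv[ok])) < 2L)
        return(c(rho = NA_real_, p = NA_real_, n = n))
    rho <- cor(xv[ok], yv[ok], method = "spearman")
    if (abs(rho) >= 1)
        return(c(rho = rho, p = 0, n = n))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho = rho, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Spearman correlation of proteins with clinical scores
#'
#' Correlates each protein's NPX level with a clinical score (NIHSS or ESRS)
#' over treatment-arm samples. The default scope, `"treatment_pooled"`,
#' pools the arm's baseline and post samples into one correlation (each
#' subject contributes both observations, treated as independent — the
#' convention flagged in the package documentation, not a statistical
#' endorsement); `"per_timepoint"` returns a separate record per timepoint.
#' rho uses average ranks for ties; p is the t-approximation on n - 2 df.
#' Constant protein or constant score yields an NA record.
#'
#' @param x an [NPXExperiment-class] whose `colData` carries the score.
#' @param design a [StudyDesign-class].
#' @param score `"nihss"` or `"esrs"`.
#' @param scope `"treatment_pooled"` (default) or `"per_timepoint"`.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame with `assay_id`, (`timepoint` when per-timepoint),
#'   `score`, `rho`, `p`, `n`, `significant`.
#' @export
spearmanScores <- function(x, design, score = c("nihss", "esrs"),
                           scope = c("treatment_pooled", "per_timepoint"),
                           alpha = 0.05) {
    score <- match.arg(score)
    scope <- match.arg(scope)
    cd <- colData(x)
    if (!score %in% colnames(cd))
        stop("score column '", score, "' absent from sample annotations")
    m <- npxValues(x)
    run <- function(ids, tp) {
        sc <- as.numeric(cd[[score]][match(ids, cd$sample_id)])
        rec <- t(apply(m[, ids, drop = FALSE], 1L, .spearmanRecord, yv = sc))
        out <- data.frame(assay_id = rownames(m), score = score,
                          rho = rec[, "rho"], p = rec[, "p"],
                          n = as.integer(rec[, "n"]),
                          row.names = NULL, stringsAsFactors = FALSE)
        if (!is.null(tp)) out$timepoint <- tp
        out$significant <- !is.na(out$p) & out$p < alpha
        out
    }
    g <- designGroups(design)
    if (scope == "treatment_pooled")
        run(c(g$T1, g$T2), NULL)
    else
        rbind(run(g$T1, "baseline"), run(g$T2, "post"))
}

#' Overlap of score-correlated proteins with the screening core
#'
#' Intersects the proteins significantly correlated with a clinical score
#' with the core treatment-specific set, ordered by |rho| decreasing.
#'
#' @param correlations output of [spearmanScores()].
#' @param sets a [ScreenSets-class].
#' @return list with `proteins` (character, sorted by |rho|) and `count`.
#' @export
overlapWithCore <- function(correlations, sets) {
    sig <- correlations[correlations$significant %in% TRUE, , drop = FALSE]
    hit <- sig[sig$assay_id %in% screenSet(sets, "core"), , drop = FALSE]
    hit <- hit[order(-abs(hit$rho)), , drop = FALSE]
    list(proteins = unique(hit$assay_id), count = length(unique(hit$assay_id)))
}

#' Sex-stratified protein comparison with FDR control
#'
#' Compares NPX levels between male and female participants at one
#' timepoint, per protein, using a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test by default or Welch's t-test; Benjamini-Hochberg
#' adjustment across the panel; `significant_after_fdr` at q < 0.05.
#'
#' @param x an [NPXExperiment-class] with a `sex` annotation.
#' @param design a [StudyDesign-class] (unused beyond argument symmetry;
#'   the comparison runs over all samples at the timepoint).
#' @param timepoint `"baseline"` or `"post"`.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return data.frame with `assay_id`, `timepoint`, `n_male`, `n_female`,
#'   `p`, `q`, `significant_after_fdr`.
#' @export
sexComparison <- function(x, design, timepoint = c("baseline", "post"),
                          test = c("wilcoxon", "welch")) {
    timepoint <- match.arg(timepoint)
    test <- match.arg(test)
    cd <- colData(x)
    if (!"sex" %in% colnames(cd))
        stop("no 'sex' annotation")
    sel <- cd$timepoint == timepoint
    sex <- as.character(cd$sex[sel])
    if (!all(c("male", "female") %in% sex))
        stop("both sexes must be represented at timepoint '", timepoint, "'")
    m <- npxValues(x)[, as.character(cd$sample_id[sel]), drop = FALSE]
    male <- m[, sex == "male", drop = FALSE]
    female <- m[, sex == "female", drop = FALSE]
    p <- vapply(seq_len(nrow(m)), function(i) {
        a <- male[i, !is.na(male[i, ])]
        b <- female[i, !is.na(female[i, ])]
        if (length(a) < 2L || length(b) < 2L) return(NA_real_)
        if (test == "wilcoxon")
            suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
        else
            t.test(a, b)$p.value
    }, numeric(1))
    q <- bhFdr(p)
    data.frame(assay_id = rownames(m), timepoint = timepoint,
               n_male = ncol(male), n_female = ncol(female),
               p = p, q = q,
               significant_after_fdr = !is.na(q) & q < 0.05,
               row.names = NULL, stringsAsFactors = FALSE)
}
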