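#' @importFrom stats var pt pnorm p.adjust digamma trigamma psigamma
#'   uniroot complete.cases setNames
NULL

#' Analysis configuration for contrasts, screening and downstream stages
#'
#' @param alpha per-contrast significance threshold (default 0.05).
#' @param fcCut absolute log2 fold-change threshold used by the
#'   `"p_and_fc"` labeling rule (default 0.5). NPX is log2-scale, so the
#'   effect estimate is the log2FC directly.
#' @param membershipRule how screening-set membership calls significance:
#'   `"p_only"` (p < alpha; the default) or `"p_and_fc"` (additionally
#'   |log2FC| > fcCut, the volcano labeling rule).
#' @param pairedModel `"difference"` (one-sample moderated test on
#'   within-subject post-minus-pre differences) or `"blocked"`; for the
#'   complete balanced pairs that enter paired contrasts the two are
#'   algebraically identical, so both values run the same computation.
#' @param nTrees,mtry random-forest settings (`mtry = NULL` means the
#'   package default, floor(sqrt(p)) for classification).
#' @param seed integer seed for seeded stages (random forest).
#' @return a list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(alpha = 0.05, fcCut = 0.5,
                           membershipRule = c("p_only", "p_and_fc"),
                           pairedModel = c("difference", "blocked"),
                           nTrees = 500L, mtry = NULL, seed = 1L) {
    stopifnot(alpha > 0, alpha < 1, fcCut >= 0)
    cfg <- list(alpha = alpha, fcCut = fcCut,
                membershipRule = match.arg(membershipRule),
                pairedModel = match.arg(pairedModel),
                nTrees = as.integer(nTrees), mtry = mtry,
                seed = as.integer(seed))
    class(cfg) <- "AnalysisConfig"
    cfg
}

#' Per-protein ordinary statistics for one contrast
#'
#' Computes, for every protein, the raw ingredients of the moderated test.
#' Unpaired (group A vs group B): effect = mean(A) - mean(B), s2 = pooled
#' variance, d = nA + nB - 2, u = sqrt(1/nA + 1/nB). Paired (post vs pre
#' within one arm): per-subject differences D = post - pre over complete
#' pairs, effect = mean(D), s2 = var(D), d = n - 1, u = sqrt(1/n). Only
#' complete observations (complete pairs) contribute; a protein failing the
#' minimum (2 observations per group, or 2 complete pairs) is dropped and
#' listed in `attr(, "dropped")` with a reason.
#'
#' @param x an [NPXExperiment-class].
#' @param design a [StudyDesign-class] from [validateDesign()].
#' @param contrast one element of [contrastSpecs()], or any list with fields
#'   `name`, `paired`, and either `groups = c(A, B)` (unpaired, effect
#'   oriented A minus B) or `arm` (paired, effect oriented post minus pre).
#' @return data.frame with columns `assay_id`, `beta_hat`, `s2`, `d`, `u`,
#'   `n` (observations used); attribute `dropped` is a named character
#'   vector of excluded proteins.
#' @export
ordinaryStats <- function(x, design, contrast) {
    stopifnot(is(x, "NPXExperiment"), is(design, "StudyDesign"))
    m <- npxValues(x)
    if (isTRUE(contrast$paired)) {
        arm <- contrast$arm
        subj <- pairedSubjects(design)[[arm]]
        if (!length(subj))
            stop("no paired subjects in arm '", arm, "'")
        cd <- colData(x)
        pick <- function(tp) {
            sel <- cd$arm == arm & cd$timepoint == tp
            ids <- as.character(cd$sample_id[sel])
            sj <- as.character(cd$subject_id[sel])
            ids[match(subj, sj)]  # sample ids in paired-subject order
        }
        pre <- m[, pick("baseline"), drop = FALSE]
        post <- m[, pick("post"), drop = FALSE]
        D <- post - pre  # columns follow the paired subject order
        n <- rowSums(!is.na(D))
        beta_hat <- rowMeans(D, na.rm = TRUE)
        s2 <- apply(D, 1L, var, na.rm = TRUE)
        d <- n - 1
        u <- sqrt(1 / n)
    } else {
        ga <- designGroups(design)[[contrast$groups[1]]]
        gb <- designGroups(design)[[contrast$groups[2]]]
        if (!length(ga) || !length(gb))
            stop("empty contrast group in ", contrast$name)
        a <- m[, ga, drop = FALSE]
        b <- m[, gb, drop = FALSE]
        na_ <- rowSums(!is.na(a))
        nb_ <- rowSums(!is.na(b))
        beta_hat <- rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE)
        va <- apply(a, 1L, var, na.rm = TRUE)
        vb <- apply(b, 1L, var, na.rm = TRUE)
        s2 <- ((na_ - 1) * va + (nb_ - 1) * vb) / (na_ + nb_ - 2)
        d <- na_ + nb_ - 2
        u <- sqrt(1 / na_ + 1 / nb_)
        n <- na_ + nb_
        low <- na_ < 2 | nb_ < 2
        d[low] <- 0  # flag for dropping below
    }
    keep <- is.finite(beta_hat) & d >= 1 & is.finite(s2)
    out <- data.frame(assay_id = rownames(m), beta_hat = beta_hat,
                      s2 = s2, d = d, u = u, n = n,
                      row.names = NULL, stringsAsFactors = FALSE)[keep, ]
    dropped <- setNames(rep("insufficient complete observations",
                            sum(!keep)), rownames(m)[!keep])
    if (length(dropped))
        message(contrast$name, ": dropped ", length(dropped),
                " protein(s) with insufficient data")
    attr(out, "dropped") <- dropped
    attr(out, "contrast") <- contrast$name
    out
}

# inverse of trigamma by Newton iteration on 1/x scale (monotone, convex)
.trigammaInverse <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, 2L)
        x <- x + dif
        if (abs(dif) / x < 1e-10) break
    }
    x
}

#' Fit the empirical-Bayes variance prior by method of moments
#'
#' Models the per-protein residual variances s2_g as scaled inverse-chi-square
#' draws around a prior variance s0^2 with d0 prior degrees of freedom, and
#' estimates (d0, s0^2) by matching moments of z_g = log(s2_g):
#' e_g = z_g - digamma(d_g/2) + log(d_g/2); the excess dispersion of e over
#' its sampling variance trigamma(d_g/2) determines d0 through
#' trigamma(d0/2) = mean_g[(e_g - mean(e))^2 G/(G-1) - trigamma(d_g/2)], and
#' s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). When the dispersion
#' excess is non-positive the prior is degenerate: d0 = Inf and
#' s0^2 = exp(mean(e)).
#'
#' Proteins with s2 = 0 cannot enter the log-scale fit and are excluded from
#' the moment equations (they are still shrunk by [moderatedTest()]); all
#' variances zero is an error.
#'
#' @param stats output of [ordinaryStats()].
#' @return list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fitEbayesPrior <- function(stats) {
    ok <- stats$s2 > 0 & stats$d >= 1
    if (sum(stats$d >= 1) < 2L)
        stop("need at least 2 proteins with residual df >= 1 to moderate")
    if (!any(ok))
        stop("all residual variances are zero; degenerate data")
    s2 <- stats$s2[ok]
    d <- stats$d[ok]
    G <- length(s2)
    if (G < 2L)
        stop("need at least 2 proteins with positive variance to moderate")
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(d / 2))
    if (rhs <= 0)
        return(list(d0 = Inf, s0_sq = exp(ebar)))
    d0 <- 2 * .trigammaInverse(rhs)
    list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated t-test with a shrunken variance
#'
#' Shrinks each protein's residual variance toward the prior,
#' s2_tilde = (d0 s0^2 + d s2) / (d0 + d), and tests effect / (s_tilde u)
#' against Student's t with d0 + d degrees of freedom (standard normal when
#' d0 = Inf; the classic unmoderated t when d0 = 0).
#'
#' @param stats output of [ordinaryStats()].
#' @param prior output of [fitEbayesPrior()] (or any list with `d0`,
#'   `s0_sq`).
#' @return data.frame with `assay_id`, `beta_hat` (log2FC), `t_mod`,
#'   `df_total`, `p`, `q` (BH across the tested proteins); the `dropped`
#'   attribute of `stats` is propagated.
#' @export
moderatedTest <- function(stats, prior) {
    stopifnot(all(c("d0", "s0_sq") %in% names(prior)), prior$s0_sq > 0)
    d0 <- prior$d0
    if (is.infinite(d0)) {
        s2_tilde <- rep(prior$s0_sq, nrow(stats))
        df_total <- rep(Inf, nrow(stats))
    } else {
        s2_tilde <- (d0 * prior$s0_sq + stats$d * stats$s2) / (d0 + stats$d)
        df_total <- d0 + stats$d
    }
    t_mod <- stats$beta_hat / (sqrt(s2_tilde) * stats$u)
    p <- ifelse(is.infinite(df_total),
                2 * pnorm(-abs(t_mod)),
                2 * pt(-abs(t_mod), df_total))
    out <- data.frame(assay_id = stats$assay_id, beta_hat = stats$beta_hat,
                      t_mod = t_mod, df_total = df_total, p = p,
                      q = p.adjust(p, method = "BH"),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "dropped") <- attr(stats, "dropped")
    attr(out, "contrast") <- attr(stats, "contrast")
    attr(out, "prior") <- prior
    out
}

#' Classify proteins as up / down / not significant
#'
#' Rule `"p_only"`: up iff p < alpha and effect > 0 (down symmetric);
#' rule `"p_and_fc"` additionally requires |log2FC| > fcCut — the volcano
#' labeling convention. Ties at exactly alpha are not significant.
#'
#' @param result a contrast result from [moderatedTest()].
#' @param config an [analysisConfig()] (supplies `alpha` and `fcCut`).
#' @param rule overrides `config$membershipRule` when given.
#' @return `result` with a `direction` factor column added; counts in
#'   `attr(, "counts")` (up, down, ns).
#' @export
classifyDeps <- function(result, config = analysisConfig(), rule = NULL) {
    rule <- if (is.null(rule)) config$membershipRule else
        match.arg(rule, c("p_only", "p_and_fc"))
    sig <- result$p < config$alpha
    if (rule == "p_and_fc")
        sig <- sig & abs(result$beta_hat) > config$fcCut
    direction <- ifelse(!sig, "ns", ifelse(result$beta_hat > 0, "up", "down"))
    result$direction <- factor(direction, levels = c("up", "down", "ns"))
    attr(result, "counts") <- table(result$direction)
    attr(result, "rule") <- rule
    result
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotone enforcement, preserving input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in the same order.
#' @export
bhFdr <- function(pvalues) {
    if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}
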