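#' The six study contrasts
#'
#' The analysis framework runs four unpaired inter-group comparisons and two
#' paired within-arm longitudinal comparisons over the four study cells
#' (T1/T2 = treatment baseline/post, C1/C2 = control baseline/post):
#' G1 = T2 vs C1, G2 = C2 vs T1, G3 = T1 vs C1, G4 = T2 vs C2 (unpaired,
#' effect oriented first-named minus second), P1 = T2 vs T1 within the
#' treatment arm and P2 = C2 vs C1 within the control arm (paired, post
#' minus pre). G3, G4, P1 and P2 feed the screening algebra; G1 and G2 are
#' descriptive.
#'
#' @return named list of contrast specifications, each with `name`,
#'   `paired`, and `groups` (unpaired) or `arm` (paired).
#' @export
contrastSpecs <- function() {
    list(G1 = list(name = "G1", paired = FALSE, groups = c("T2", "C1")),
         G2 = list(name = "G2", paired = FALSE, groups = c("C2", "T1")),
         G3 = list(name = "G3", paired = FALSE, groups = c("T1", "C1")),
         G4 = list(name = "G4", paired = FALSE, groups = c("T2", "C2")),
         P1 = list(name = "P1", paired = TRUE, arm = "treatment"),
         P2 = list(name = "P2", paired = TRUE, arm = "control"))
}

#' Run all six contrasts with per-contrast empirical-Bayes moderation
#'
#' For each contrast: ordinary statistics ([ordinaryStats()]), a prior
#' fitted from that contrast's own residual variances ([fitEbayesPrior()]),
#' the moderated test ([moderatedTest()]), and direction labels
#' ([classifyDeps()] under `config$membershipRule`). Orientation: a positive
#' effect means higher in the first-named group (T2 in G1/G4/P1, C2 in
#' G2/P2, T1 in G3).
#'
#' @param x an [NPXExperiment-class].
#' @param design a [StudyDesign-class].
#' @param config an [analysisConfig()].
#' @param contrasts subset of contrast names to run (default all six).
#' @return named list of classified contrast result data.frames.
#' @export
runContrasts <- function(x, design, config = analysisConfig(),
                         contrasts = names(contrastSpecs())) {
    specs <- contrastSpecs()[contrasts]
    lapply(specs, function(sp) {
        st <- ordinaryStats(x, design, sp)
        classifyDeps(moderatedTest(st, fitEbayesPrior(st)), config)
    })
}

.significantSet <- function(result, alpha, rule, fcCut) {
    sig <- result$p < alpha
    if (rule == "p_and_fc")
        sig <- sig & abs(result$beta_hat) > fcCut
    result$assay_id[sig]
}

#' Build the triple orthogonal screening sets
#'
#' The screen combines four contrasts to isolate treatment-specific
#' proteins. Over the universe of proteins tested in all of G3, G4, P1 and
#' P2 (proteins dropped from any constituent contrast are excluded and
#' recorded):
#'
#' * set1 — no detectable baseline difference (G3 p > alpha) but an
#'   inter-group difference after intervention (G4 significant);
#' * set2 — time-dependent proteins: significant in the control arm's
#'   paired contrast P2;
#' * set3 — treatment-responsive proteins: significant in the treatment
#'   arm's paired contrast P1;
#' * set4 = set1 \ set2 — removes time-dependent proteins from set1;
#' * set5 = set1 intersect set3;
#' * core = set3 intersect set4 intersect set5, equivalently
#'   (set1 intersect set3) \ set2 — the treatment-specific candidates.
#'
#' Significance is strict (p < alpha) and baseline-null eligibility strict
#' the other way (p > alpha), so a p exactly at alpha is neither; under the
#' `"p_and_fc"` rule significance additionally requires |log2FC| > fcCut and
#' baseline-null eligibility is the negation of that rule's significance.
#'
#' @param results named list from [runContrasts()], containing at least
#'   G3, G4, P1, P2.
#' @param config an [analysisConfig()].
#' @return a [ScreenSets-class].
#' @export
buildScreenSets <- function(results, config = analysisConfig()) {
    need <- c("G3", "G4", "P1", "P2")
    miss <- setdiff(need, names(results))
    if (length(miss))
        stop("missing contrast result(s): ", paste(miss, collapse = ", "))
    rule <- config$membershipRule
    universe <- Reduce(intersect, lapply(results[need], `[[`, "assay_id"))
    res <- lapply(results[need], function(r)
        r[match(universe, r$assay_id), , drop = FALSE])
    ties <- vapply(res, function(r) sum(r$p == config$alpha), integer(1))
    if (any(ties > 0))
        message("p-values exactly at alpha in ",
                paste(names(ties)[ties > 0], collapse = ", "),
                "; treated as non-significant and non-null-eligible")
    sig <- lapply(res, .significantSet, alpha = config$alpha, rule = rule,
                  fcCut = config$fcCut)
    baseline_null <- if (rule == "p_only")
        universe[res$G3$p > config$alpha]
    else
        setdiff(universe, sig$G3)
    set1 <- intersect(baseline_null, sig$G4)
    set2 <- sig$P2
    set3 <- sig$P1
    obj <- new("ScreenSets",
               set1 = set1, set2 = set2, set3 = set3,
               set4 = setdiff(set1, set2),
               set5 = intersect(set1, set3),
               core = intersect(set3,
                                intersect(setdiff(set1, set2),
                                          intersect(set1, set3))),
               universe = universe, alpha = config$alpha,
               membershipRule = rule)
    validObject(obj)
    obj
}

#' Evaluate screen recovery against simulation truth
#'
#' Compares the recovered core set with the planted protein classes:
#' sensitivity = fraction of treatment_specific proteins in the core;
#' specificity = fraction of non-treatment_specific proteins kept out of the
#' core; plus separate leakage rates for the time_dependent and mixed
#' classes (the screen is designed to exclude both: time_dependent through
#' set2, mixed because its time component also trips set2).
#'
#' @param sets a [ScreenSets-class].
#' @param truth a [SimulationTruth-class] over the same protein universe.
#' @return list with `sensitivity`, `specificity`, `leakage_time_dependent`,
#'   `leakage_mixed`, and a `confusion` table of class vs core membership.
#' @export
evaluateRecovery <- function(sets, truth) {
    tr <- truthTable(truth)
    if (!all(screenUniverse(sets) %in% tr$assay_id))
        stop("screen universe contains proteins absent from truth")
    tr <- tr[tr$assay_id %in% screenUniverse(sets), , drop = FALSE]
    in_core <- tr$assay_id %in% screenSet(sets, "core")
    rate <- function(cls) {
        n <- sum(tr$class == cls)
        if (n == 0L) NA_real_ else sum(in_core & tr$class == cls) / n
    }
    ts <- rate("treatment_specific")
    non_ts <- tr$class != "treatment_specific"
    list(sensitivity = ts,
         specificity = if (any(non_ts))
             1 - sum(in_core & non_ts) / sum(non_ts) else NA_real_,
         leakage_time_dependent = rate("time_dependent"),
         leakage_mixed = rate("mixed"),
         confusion = table(class = tr$class, in_core = in_core))
}
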