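#' @importFrom randomForest randomForest importance
NULL

#' Random-forest importance ranking of candidate proteins
#'
#' Trains a seeded random forest to discriminate pre- from post-intervention
#' samples of the treatment arm (or treatment from control samples, with
#' `target = "arm"`) using the given proteins as features, and ranks them by
#' out-of-bag permutation importance (mean decrease in accuracy) and by
#' total impurity reduction (mean decrease in Gini). Defaults follow the
#' conventional forest settings: 500 trees, floor(sqrt(p)) candidate
#' variables per split, out-of-bag evaluation. The same seed reproduces the
#' ranking exactly.
#'
#' Samples with any missing value among the selected features are excluded
#' (no imputation anywhere in the pipeline).
#'
#' @param x an [NPXExperiment-class].
#' @param design a [StudyDesign-class].
#' @param features character vector of protein ids to rank.
#' @param config an [analysisConfig()] (supplies `nTrees`, `mtry`, `seed`).
#' @param target classification label: `"timepoint"` (default; pre vs post
#'   within the treatment arm) or `"arm"` (all samples).
#' @return data.frame with `assay_id`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`, `rank_mda`, `rank_gini`, ordered by `rank_mda`.
#' @export
rfImportance <- function(x, design, features, config = analysisConfig(),
                         target = c("timepoint", "arm")) {
    target <- match.arg(target)
    miss <- setdiff(features, assayIds(x))
    if (length(miss))
        stop("feature(s) absent from panel: ", paste(miss, collapse = ", "))
    cd <- colData(x)
    if (target == "timepoint") {
        ids <- as.character(cd$sample_id[cd$arm == "treatment"])
        label <- factor(as.character(cd$timepoint[cd$arm == "treatment"]),
                        levels = TIMEPOINT_LEVELS)
    } else {
        ids <- as.character(cd$sample_id)
        label <- factor(as.character(cd$arm), levels = ARM_LEVELS)
    }
    feat <- t(npxValues(x)[features, ids, drop = FALSE])
    ok <- complete.cases(feat)
    feat <- feat[ok, , drop = FALSE]
    label <- droplevels(label[ok])
    if (nlevels(label) < 2L || any(table(label) < 4L))
        stop("need at least 4 samples per class for importance ranking")
    mtry <- if (is.null(config$mtry)) floor(sqrt(ncol(feat))) else config$mtry
    set.seed(config$seed)
    fit <- randomForest(x = as.data.frame(feat), y = label,
                        ntree = config$nTrees, mtry = mtry,
                        importance = TRUE)
    imp <- importance(fit)
    mda <- imp[, "MeanDecreaseAccuracy"]
    gini <- imp[, "MeanDecreaseGini"]
    out <- data.frame(assay_id = features,
                      mean_decrease_accuracy = unname(mda),
                      mean_decrease_gini = unname(gini),
                      rank_mda = rank(-mda, ties.method = "first"),
                      rank_gini = rank(-gini, ties.method = "first"),
                      row.names = NULL, stringsAsFactors = FALSE)
    out[order(out$rank_mda), , drop = FALSE]
}
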