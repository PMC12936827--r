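#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData colData<-
NULL

ARM_LEVELS <- c("treatment", "control")
TIMEPOINT_LEVELS <- c("baseline", "post")
SEX_LEVELS <- c("male", "female", "unknown")

#' Container for an NPX protein-by-sample matrix with study annotations
#'
#' `NPXExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' one assay, `"npx"`, holding log2-scale NPX values (proteins in rows,
#' samples in columns; `NA` marks a missing cell). `rowData` carries the
#' protein annotation (`assay_id`, `gene_symbol`, optionally `uniprot_id`,
#' `panel_name`); `colData` carries the per-sample study annotation
#' (`sample_id`, `subject_id`, `arm`, `timepoint`, and optionally `sex`,
#' `age`, `nihss`, `esrs`).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [NPXExperiment()] for the constructor, [readNpxLong()] to build
#'   one from long-format files, [validateDesign()] for the group/pairing
#'   structure.
#' @export
setClass("NPXExperiment", contains = "SummarizedExperiment")

setValidity("NPXExperiment", function(object) {
    msg <- character()
    if (!"npx" %in% names(assays(object)))
        msg <- c(msg, "assay 'npx' is required")
    rd <- rowData(object)
    cd <- colData(object)
    if (!all(c("assay_id", "gene_symbol") %in% colnames(rd)))
        msg <- c(msg, "rowData must have 'assay_id' and 'gene_symbol'")
    else {
        if (anyDuplicated(rd$assay_id))
            msg <- c(msg, "duplicated assay_id in rowData")
        if (any(!nzchar(rd$gene_symbol)))
            msg <- c(msg, "empty gene_symbol in rowData")
    }
    need <- c("sample_id", "subject_id", "arm", "timepoint")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, sprintf("colData must have columns: %s",
                              paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "duplicated sample_id in colData")
        if (!all(cd$arm %in% ARM_LEVELS))
            msg <- c(msg, sprintf("arm must be one of: %s",
                                  paste(ARM_LEVELS, collapse = ", ")))
        if (!all(cd$timepoint %in% TIMEPOINT_LEVELS))
            msg <- c(msg, sprintf("timepoint must be one of: %s",
                                  paste(TIMEPOINT_LEVELS, collapse = ", ")))
        if (anyDuplicated(cd[, c("subject_id", "timepoint"), drop = FALSE]))
            msg <- c(msg, "duplicated (subject_id, timepoint) pair")
        if ("sex" %in% colnames(cd) && !all(cd$sex %in% SEX_LEVELS))
            msg <- c(msg, sprintf("sex must be one of: %s",
                                  paste(SEX_LEVELS, collapse = ", ")))
        if ("nihss" %in% colnames(cd)) {
            v <- cd$nihss[!is.na(cd$nihss)]
            if (length(v) && (any(v < 0) || any(v > 42)))
                msg <- c(msg, "nihss outside [0, 42]")
        }
        if ("esrs" %in% colnames(cd)) {
            v <- cd$esrs[!is.na(cd$esrs)]
            if (length(v) && (any(v < 0) || any(v > 9)))
                msg <- c(msg, "esrs outside [0, 9]")
        }
    }
    v <- assay(object, "npx")
    if (any(is.infinite(v)))
        msg <- c(msg, "non-missing NPX values must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct an NPXExperiment
#'
#' @param npx numeric matrix, proteins x samples, log2-scale NPX; `NA` for
#'   missing cells. Row names are assay ids, column names sample ids (taken
#'   from `proteins`/`samples` if absent).
#' @param proteins data.frame/DataFrame with at least `assay_id` and
#'   `gene_symbol` (defaults `gene_symbol` to `assay_id`).
#' @param samples data.frame/DataFrame with at least `sample_id`,
#'   `subject_id`, `arm` (`"treatment"`/`"control"`), `timepoint`
#'   (`"baseline"`/`"post"`); optional `sex`, `age`, `nihss`, `esrs`.
#' @return an [NPXExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(8), 2, 4, dimnames = list(
#'     c("p1", "p2"), c("s1", "s2", "s3", "s4")))
#' ann <- data.frame(sample_id = colnames(m),
#'                   subject_id = c("u1", "u1", "u2", "u2"),
#'                   arm = c("treatment", "treatment", "control", "control"),
#'                   timepoint = c("baseline", "post", "baseline", "post"))
#' NPXExperiment(m, samples = ann)
#' @export
NPXExperiment <- function(npx, proteins = NULL, samples = NULL) {
    npx <- as.matrix(npx)
    storage.mode(npx) <- "double"
    if (is.null(proteins)) {
        if (is.null(rownames(npx)))
            stop("'proteins' or rownames(npx) required")
        proteins <- DataFrame(assay_id = rownames(npx))
    }
    proteins <- as(proteins, "DataFrame")
    if (!"gene_symbol" %in% colnames(proteins))
        proteins$gene_symbol <- proteins$assay_id
    if (is.null(samples))
        stop("'samples' annotation is required")
    samples <- as(samples, "DataFrame")
    for (col in c("arm", "timepoint", "sex"))
        if (col %in% colnames(samples))
            samples[[col]] <- as.character(samples[[col]])
    rownames(npx) <- proteins$assay_id
    colnames(npx) <- samples$sample_id
    se <- SummarizedExperiment(assays = list(npx = npx),
                               rowData = proteins, colData = samples)
    new("NPXExperiment", se)
}

#' Four-group pairing structure of a two-arm, two-timepoint study
#'
#' Produced by [validateDesign()]. Partitions samples into the four cells
#' T1 (treatment baseline), T2 (treatment post), C1 (control baseline),
#' C2 (control post); records which subjects contribute a complete
#' baseline/post pair per arm and which are unpaired (present at only one
#' timepoint, excluded from paired contrasts only).
#'
#' @slot groups named list of sample-id character vectors for T1, T2, C1, C2.
#' @slot pairedSubjects named list (`treatment`, `control`) of subject ids
#'   with both timepoints.
#' @slot unpairedSubjects character vector of subjects lacking one timepoint.
#' @export
setClass("StudyDesign", representation(
    groups = "list",
    pairedSubjects = "list",
    unpairedSubjects = "character"
))

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (!identical(sort(names(object@groups)), sort(c("T1", "T2", "C1", "C2"))))
        msg <- c(msg, "groups must be named T1, T2, C1, C2")
    all_ids <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(all_ids))
        msg <- c(msg, "groups must be disjoint")
    if (!identical(sort(names(object@pairedSubjects)),
                   sort(c("treatment", "control"))))
        msg <- c(msg, "pairedSubjects must be named treatment, control")
    if (length(msg)) msg else TRUE
})

#' Result of the triple orthogonal screening set algebra
#'
#' Holds the five screening sets and the core treatment-specific set, together
#' with the thresholds under which membership was decided. The defining
#' algebra (with `sig(X)` the significant proteins of contrast X at the
#' recorded `alpha` and membership rule):
#' set1 = not-sig(G3) and sig(G4); set2 = sig(P2); set3 = sig(P1);
#' set4 = set1 minus set2; set5 = set1 intersect set3;
#' core = set3 intersect set4 intersect set5 = (set1 intersect set3) minus set2.
#'
#' @slot set1,set2,set3,set4,set5,core character vectors of protein ids.
#' @slot universe character, proteins tested in all constituent contrasts.
#' @slot alpha numeric significance threshold used.
#' @slot membershipRule `"p_only"` or `"p_and_fc"`.
#' @seealso [buildScreenSets()]
#' @export
setClass("ScreenSets", representation(
    set1 = "character", set2 = "character", set3 = "character",
    set4 = "character", set5 = "character", core = "character",
    universe = "character", alpha = "numeric", membershipRule = "character"
))

setValidity("ScreenSets", function(object) {
    msg <- character()
    if (!all(object@set4 %in% object@set1))
        msg <- c(msg, "set4 must be a subset of set1")
    if (!setequal(object@set5, intersect(object@set1, object@set3)))
        msg <- c(msg, "set5 must equal set1 intersect set3")
    if (!setequal(object@core,
                  setdiff(intersect(object@set1, object@set3), object@set2)))
        msg <- c(msg, "core must equal (set1 n set3) \\ set2")
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be a single value in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' @slot proteins DataFrame with one row per protein: `assay_id`, `class`
#'   (null / treatment_specific / time_dependent / baseline_shifted / mixed),
#'   `mu`, and the planted effects `delta` (treatment-by-post interaction),
#'   `gamma` (time drift), `beta` (arm-baseline offset), all in NPX units.
#' @slot subjectEffects numeric matrix proteins x subjects of the random
#'   effects u_gs shared by a subject's two samples.
#' @slot seed integer seed the cohort was generated from.
#' @seealso [simulateCohort()], [evaluateRecovery()]
#' @export
setClass("SimulationTruth", representation(
    proteins = "DataFrame",
    subjectEffects = "matrix",
    seed = "integer"
))

setValidity("SimulationTruth", function(object) {
    tr <- object@proteins
    msg <- character()
    need <- c("assay_id", "class", "mu", "delta", "gamma", "beta")
    if (!all(need %in% colnames(tr)))
        return(sprintf("proteins must have columns: %s",
                       paste(need, collapse = ", ")))
    bad_delta <- tr$delta != 0 & !tr$class %in% c("treatment_specific", "mixed")
    bad_gamma <- tr$gamma != 0 & !tr$class %in% c("time_dependent", "mixed")
    bad_beta <- tr$beta != 0 & tr$class != "baseline_shifted"
    if (any(bad_delta)) msg <- c(msg, "nonzero delta outside its classes")
    if (any(bad_gamma)) msg <- c(msg, "nonzero gamma outside its classes")
    if (any(bad_beta)) msg <- c(msg, "nonzero beta outside its classes")
    if (nrow(tr) != nrow(object@subjectEffects))
        msg <- c(msg, "subjectEffects rows must match proteins")
    if (length(msg)) msg else TRUE
})
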