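#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
#' @importFrom utils packageVersion head
NULL

# deterministic per-stage seed fan-out: global seed + polynomial hash of the
# stage name, folded into the 31-bit integer range
.stageSeed <- function(seed, stage) {
    h <- 0
    for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
    as.integer((as.numeric(seed) * 10007 + h) %% (2^31 - 1))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
}

.asSimulationConfig <- function(blk) {
    args <- list()
    map <- c(n_treatment = "nTreatment", n_control = "nControl",
             n_proteins = "nProteins", delta = "delta", gamma = "gamma",
             beta = "beta", tau = "tau", sigma = "sigma", seed = "seed",
             fixed_signs = "fixedSigns")
    for (k in names(map))
        if (!is.null(blk[[k]])) args[[map[[k]]]] <- blk[[k]]
    if (!is.null(blk$class_counts))
        args$classCounts <- unlist(blk$class_counts)
    if (!is.null(blk$mu_range)) args$muRange <- unlist(blk$mu_range)
    do.call(simulationConfig, args)
}

.asAnalysisConfig <- function(blk, seed) {
    args <- list(seed = seed)
    map <- c(alpha = "alpha", fc_cut = "fcCut",
             membership_rule = "membershipRule",
             paired_model = "pairedModel", n_trees = "nTrees", mtry = "mtry")
    for (k in names(map))
        if (!is.null(blk[[k]])) args[[map[[k]]]] <- blk[[k]]
    do.call(analysisConfig, args)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in order: input (reading NPX/annotation files, or simulating a
#' cohort when the config has a `simulation` block), the six contrasts with
#' per-contrast empirical-Bayes moderation, the triple orthogonal screen,
#' clinical-score correlations and their overlap with the core set,
#' sex-stratified comparisons (when a `sex` annotation exists), random-forest
#' importance ranking of the treatment-arm paired-contrast DEPs, and — when a
#' GMT file is configured — over-representation analysis of sets 3/4/5 and
#' the core with a Venn partition of significant terms. All result tables
#' are written as TSV with a stable column order, plus `summary.json`
#' (cardinalities of sets 1-5 and core, DEP counts per contrast under both
#' membership rules) and `manifest.json` (config snapshot, input digests,
#' per-stage row counts, output digests). One global seed fans out to
#' per-stage seeds deterministically by stage name, so changing only the
#' enrichment inputs leaves upstream outputs byte-identical.
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Recognised blocks: `input` (`npx`, `annotation`), `simulation`
#'   (fields of [simulationConfig()], snake_case), `analysis` (fields of
#'   [analysisConfig()], snake_case), `enrichment` (`gmt`), plus top-level
#'   `seed` and `out_dir`.
#' @param outDir output directory (overrides `config$out_dir`).
#' @param seed global seed (overrides `config$seed`).
#' @return invisibly, a list with the in-memory results (`experiment`,
#'   `design`, `contrasts`, `sets`, `correlations`, `importance`, ...,
#'   `manifest`).
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
    if (is.character(config)) config <- read_yaml(config)
    if (is.null(outDir)) outDir <- config$out_dir
    if (is.null(outDir)) stop("no output directory configured")
    if (is.null(seed)) seed <- config$seed
    if (is.null(seed)) seed <- 1L
    seed <- as.integer(seed)
    if (is.null(config$input) && is.null(config$simulation))
        stop("config must provide either an 'input' block or a ",
             "'simulation' block")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = seed,
                     package_version = as.character(
                         packageVersion("orthoscreen")),
                     config = config, inputs = list(), stages = list(),
                     outputs = list())
    outputs <- character()
    emit <- function(df, name) {
        p <- .writeTsv(df, file.path(outDir, name))
        outputs[[name]] <<- p
        p
    }

    truth <- NULL
    if (!is.null(config$input)) {
        npx_path <- config$input$npx
        ann_path <- config$input$annotation
        x <- readNpxLong(npx_path, ann_path)
        manifest$inputs <- list(npx = unname(md5sum(npx_path)),
                                annotation = unname(md5sum(ann_path)))
    } else {
        simcfg <- .asSimulationConfig(config$simulation)
        simcfg$seed <- .stageSeed(seed, "simulate")
        sim <- simulateCohort(simcfg)
        x <- simulateScores(sim$experiment, sim$truth, simcfg)
        truth <- sim$truth
        emit(as.data.frame(truthTable(truth)), "simulation_truth.tsv")
    }
    manifest$stages$input <- list(n_proteins = nrow(x), n_samples = ncol(x))

    design <- validateDesign(x)
    acfg <- .asAnalysisConfig(config$analysis,
                              seed = .stageSeed(seed, "rf"))
    contrasts <- runContrasts(x, design, acfg)
    for (nm in names(contrasts))
        emit(contrasts[[nm]][, c("assay_id", "beta_hat", "t_mod", "df_total",
                                 "p", "q", "direction")],
             sprintf("contrast_%s.tsv", nm))
    manifest$stages$contrasts <- lapply(contrasts, nrow)

    sets <- buildScreenSets(contrasts, acfg)
    universe <- screenUniverse(sets)
    memb <- data.frame(assay_id = universe)
    for (s in c("set1", "set2", "set3", "set4", "set5", "core"))
        memb[[s]] <- universe %in% screenSet(sets, s)
    emit(memb, "screen_sets.tsv")

    dep_counts <- function(rule) {
        vapply(contrasts, function(r)
            sum(classifyDeps(r, acfg, rule = rule)$direction != "ns"),
            integer(1))
    }
    other_rule <- setdiff(c("p_only", "p_and_fc"), acfg$membershipRule)
    sets_other <- buildScreenSets(contrasts,
                                  analysisConfig(alpha = acfg$alpha,
                                                 fcCut = acfg$fcCut,
                                                 membershipRule = other_rule))
    summary <- list(
        membership_rule = acfg$membershipRule,
        alpha = acfg$alpha,
        dep_counts = as.list(dep_counts(acfg$membershipRule)),
        dep_counts_alt_rule = as.list(dep_counts(other_rule)),
        set_sizes = lapply(stats::setNames(nm = c("set1", "set2", "set3",
                                                  "set4", "set5", "core")),
                           function(s) length(screenSet(sets, s))),
        set_sizes_alt_rule = lapply(
            stats::setNames(nm = c("set1", "set2", "set3", "set4", "set5",
                                   "core")),
            function(s) length(screenSet(sets_other, s))))

    if (!is.null(truth)) {
        rec <- evaluateRecovery(sets, truth)
        emit(as.data.frame(rec$confusion), "recovery_report.tsv")
        summary$recovery <- rec[c("sensitivity", "specificity",
                                  "leakage_time_dependent", "leakage_mixed")]
    }

    cd <- colData(x)
    correlations <- NULL
    if ("nihss" %in% colnames(cd)) {
        correlations <- rbind(spearmanScores(x, design, "nihss",
                                             alpha = acfg$alpha),
                              if ("esrs" %in% colnames(cd))
                                  spearmanScores(x, design, "esrs",
                                                 alpha = acfg$alpha))
        emit(correlations, "correlations.tsv")
        ov <- overlapWithCore(
            correlations[correlations$score == "nihss", , drop = FALSE],
            sets)
        summary$nihss_core_overlap <- ov$count
        summary$nihss_core_overlap_proteins <- ov$proteins
    }
    if ("sex" %in% colnames(cd) &&
        all(c("male", "female") %in% as.character(cd$sex))) {
        sexcmp <- rbind(sexComparison(x, design, "baseline"),
                        sexComparison(x, design, "post"))
        emit(sexcmp, "sex_comparison.tsv")
        manifest$stages$sex_comparison <- nrow(sexcmp)
    }

    importance <- NULL
    p1_deps <- screenSet(sets, "set3")
    if (length(p1_deps) >= 2L) {
        importance <- tryCatch(
            rfImportance(x, design, p1_deps, acfg),
            error = function(e) {
                message("importance ranking skipped: ", conditionMessage(e))
                NULL
            })
        if (!is.null(importance)) emit(importance, "importance.tsv")
    }

    enrich <- NULL
    if (!is.null(config$enrichment$gmt)) {
        terms <- readGmt(config$enrichment$gmt)
        manifest$inputs$gmt <- unname(md5sum(config$enrichment$gmt))
        sym <- function(ids)
            as.character(rowData(x)$gene_symbol[match(ids, assayIds(x))])
        background <- sym(universe)
        queries <- list(set3 = sym(screenSet(sets, "set3")),
                        set4 = sym(screenSet(sets, "set4")),
                        set5 = sym(screenSet(sets, "set5")),
                        core = sym(screenSet(sets, "core")))
        enrich <- lapply(queries, function(q)
            hypergeomOra(q, background, terms, alpha = acfg$alpha))
        for (nm in names(enrich))
            emit(enrich[[nm]], sprintf("enrichment_%s.tsv", nm))
        emit(intersectEnrichments(enrich[c("set3", "set4", "set5")],
                                  alpha = acfg$alpha),
             "venn_regions.tsv")
    }

    sp <- file.path(outDir, "summary.json")
    write_json(summary, sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs[["summary.json"]] <- sp
    manifest$outputs <- lapply(outputs, function(p) unname(md5sum(p)))
    mp <- file.path(outDir, "manifest.json")
    write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(experiment = x, design = design, truth = truth,
                   contrasts = contrasts, sets = sets, summary = summary,
                   correlations = correlations, importance = importance,
                   enrichment = enrich, manifest = manifest))
}

# Counts reported by the study deposited at doi:10.5281/zenodo.16551369,
# used only as the comparison column of the replication harness.
.REFERENCE_COUNTS <- list(
    dep = c(G1 = 17L, G2 = 10L, G3 = 9L, G4 = 17L, P1 = 45L, P2 = 14L),
    sets = c(set1 = 24L, set2 = 14L, set3 = 45L, set4 = 19L, set5 = 16L,
             core = 12L))

#' Recompute the deposited study's counts and compare
#'
#' Runs the full contrast-and-screening computation on locally downloaded
#' deposit files (doi:10.5281/zenodo.16551369) and prints, per DEP count and
#' set cardinality, the computed value next to the count reported with the
#' deposit, under both membership rules (`p_only` and `p_and_fc`). Exact
#' agreement depends on analysis settings the deposit does not record, so
#' the harness reports all variants rather than asserting one.
#'
#' @param npxPath,annotationPath paths to the downloaded deposit files (long
#'   NPX table and sample annotation).
#' @param alpha significance threshold (0.05).
#' @param fcCut fold-change cut for the `p_and_fc` rule (0.5).
#' @param referenceCounts reference counts to compare against; defaults to
#'   the counts reported with the deposit. Supply your own named list
#'   (`dep`, `sets`) to compare against something else.
#' @return data.frame with `quantity`, `reference`, `computed_p_only`,
#'   `computed_p_and_fc`, `agree_p_only`, `agree_p_and_fc`; printed and
#'   returned invisibly.
#' @export
replicateStudy <- function(npxPath, annotationPath, alpha = 0.05,
                           fcCut = 0.5, referenceCounts = .REFERENCE_COUNTS) {
    for (p in c(npxPath, annotationPath))
        if (!file.exists(p))
            stop("deposit file not found: ", p,
                 "\nDownload the study data from ",
                 "https://doi.org/10.5281/zenodo.16551369 first.")
    x <- readNpxLong(npxPath, annotationPath)
    design <- validateDesign(x)
    one_rule <- function(rule) {
        cfg <- analysisConfig(alpha = alpha, fcCut = fcCut,
                              membershipRule = rule)
        contrasts <- runContrasts(x, design, cfg)
        sets <- buildScreenSets(contrasts, cfg)
        deps <- vapply(contrasts, function(r) sum(r$direction != "ns"),
                       integer(1))
        sizes <- vapply(c(set1 = "set1", set2 = "set2", set3 = "set3",
                          set4 = "set4", set5 = "set5", core = "core"),
                        function(s) length(screenSet(sets, s)), integer(1))
        c(deps, sizes)
    }
    a <- one_rule("p_only")
    b <- one_rule("p_and_fc")
    ref <- c(referenceCounts$dep, referenceCounts$sets)
    out <- data.frame(quantity = names(ref),
                      reference = unname(ref),
                      computed_p_only = unname(a[names(ref)]),
                      computed_p_and_fc = unname(b[names(ref)]),
                      row.names = NULL, stringsAsFactors = FALSE)
    out$agree_p_only <- out$computed_p_only == out$reference
    out$agree_p_and_fc <- out$computed_p_and_fc == out$reference
    print(out, row.names = FALSE)
    invisible(out)
}
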