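#' @importFrom stats rnorm runif rnbinom
NULL

PROTEIN_CLASSES <- c("null", "treatment_specific", "time_dependent",
                     "baseline_shifted", "mixed")

#' Configuration of the synthetic two-arm, two-timepoint cohort
#'
#' The generator emulates a randomized pre/post trial profiled on a targeted
#' NPX panel. Each protein g belongs to one effect class; for sample s of
#' subject with treatment indicator A (1 = treatment) at timepoint with post
#' indicator P (1 = post):
#'
#' NPX_gs = mu_g + u_gs + beta_g A + gamma_g P + delta_g A P + eps,
#' u_gs ~ N(0, tau^2) shared by a subject's two samples, eps ~ N(0, sigma^2).
#'
#' Classes carry: `treatment_specific` delta only, `time_dependent` gamma
#' only, `baseline_shifted` beta only, `mixed` gamma and delta, `null`
#' nothing. Effect magnitudes come from `delta`, `gamma`, `beta`; per-protein
#' signs are drawn +/-1 with equal probability unless `fixedSigns = TRUE`
#' (then the signed config values are used as-is). Per-protein baseline means
#' mu_g are uniform on `muRange`. All randomness flows from one generator
#' seeded with `seed`, drawn in a fixed stream order: mu, signs, subject
#' effects, residuals.
#'
#' @param nTreatment,nControl subjects per arm (default 22 and 22).
#' @param nProteins panel size (default 92).
#' @param classCounts named integer vector over the five classes, summing to
#'   `nProteins`. Default: 10 treatment_specific, 10 time_dependent, 5 mixed,
#'   0 baseline_shifted, 67 null.
#' @param delta treatment-by-post interaction magnitude, NPX units (1.0).
#' @param gamma time-drift magnitude, NPX units (-0.8).
#' @param beta arm-baseline offset magnitude, NPX units (0.7).
#' @param tau subject random-effect SD, NPX units (0.5).
#' @param sigma residual SD, NPX units (0.4).
#' @param muRange range of per-protein baseline means, NPX units (c(2, 10)).
#' @param fixedSigns use the signed `delta`/`gamma`/`beta` for every carrier
#'   protein instead of random per-protein signs (default FALSE).
#' @param scoreWeights named list with elements `nihss` and `esrs`, each a
#'   named numeric vector of weights keyed by protein id (or `NULL` to pick
#'   defaults at generation: the first treatment-specific proteins, negative
#'   weights, so effective treatment lowers severity scores).
#' @param scoreNoise named numeric vector, SD of the score noise
#'   (default c(nihss = 2, esrs = 0.8)).
#' @param scoreIntercept named numeric vector (default c(nihss = 25,
#'   esrs = 7)).
#' @param seed integer seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nTreatment = 22L, nControl = 22L,
                             nProteins = 92L,
                             classCounts = NULL,
                             delta = 1.0, gamma = -0.8, beta = 0.7,
                             tau = 0.5, sigma = 0.4,
                             muRange = c(2, 10),
                             fixedSigns = FALSE,
                             scoreWeights = NULL,
                             scoreNoise = c(nihss = 2, esrs = 0.8),
                             scoreIntercept = c(nihss = 25, esrs = 7),
                             seed = 1L) {
    if (is.null(classCounts)) {
        classCounts <- c(null = nProteins - 25L, treatment_specific = 10L,
                         time_dependent = 10L, baseline_shifted = 0L,
                         mixed = 5L)
        if (nProteins < 25L)
            classCounts <- c(null = nProteins, treatment_specific = 0L,
                             time_dependent = 0L, baseline_shifted = 0L,
                             mixed = 0L)
    }
    classCounts <- classCounts[PROTEIN_CLASSES]
    classCounts[is.na(classCounts)] <- 0L
    names(classCounts) <- PROTEIN_CLASSES
    cfg <- list(nTreatment = as.integer(nTreatment),
                nControl = as.integer(nControl),
                nProteins = as.integer(nProteins),
                classCounts = as.integer(classCounts) |>
                    stats::setNames(PROTEIN_CLASSES),
                delta = delta, gamma = gamma, beta = beta,
                tau = tau, sigma = sigma, muRange = muRange,
                fixedSigns = isTRUE(fixedSigns),
                scoreWeights = scoreWeights,
                scoreNoise = scoreNoise,
                scoreIntercept = scoreIntercept,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    .validateSimConfig(cfg)
    cfg
}

.validateSimConfig <- function(cfg) {
    if (sum(cfg$classCounts) != cfg$nProteins)
        stop("classCounts must sum to nProteins (",
             sum(cfg$classCounts), " != ", cfg$nProteins, ")")
    if (cfg$nTreatment < 2L || cfg$nControl < 2L)
        stop("need at least 2 subjects per arm")
    if (any(c(cfg$tau, cfg$sigma, cfg$scoreNoise) < 0))
        stop("SDs must be non-negative")
    if (length(cfg$muRange) != 2L || diff(cfg$muRange) < 0)
        stop("muRange must be an increasing pair")
    invisible(cfg)
}

#' Simulate an NPX cohort with planted effect classes
#'
#' Generates a full two-arm, two-timepoint cohort under the model described
#' in [simulationConfig()], returning the NPX container and the complete
#' ground truth (per-protein class and effect values, per-subject random
#' effects). The same config and seed reproduce the cohort bit-identically.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @return list with elements `experiment` ([NPXExperiment-class]) and
#'   `truth` ([SimulationTruth-class]).
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 7))
#' sim$experiment
#' table(truthTable(sim$truth)$class)
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .validateSimConfig(config)
    set.seed(config$seed)
    G <- config$nProteins
    subjects <- c(sprintf("T%02d", seq_len(config$nTreatment)),
                  sprintf("C%02d", seq_len(config$nControl)))
    arm <- rep(c("treatment", "control"),
               c(config$nTreatment, config$nControl))
    S <- length(subjects)
    prot_ids <- sprintf("prot%03d", seq_len(G))
    cls <- rep(PROTEIN_CLASSES, config$classCounts)

    # stream order: mu, signs, subject effects, residuals
    mu <- runif(G, config$muRange[1], config$muRange[2])
    sgn <- if (config$fixedSigns) rep(1, G) else sample(c(-1, 1), G,
                                                        replace = TRUE)
    delta_g <- ifelse(cls %in% c("treatment_specific", "mixed"),
                      sgn * config$delta, 0)
    gamma_g <- ifelse(cls %in% c("time_dependent", "mixed"),
                      sgn * config$gamma, 0)
    beta_g <- ifelse(cls == "baseline_shifted", sgn * config$beta, 0)

    u <- matrix(rnorm(G * S, 0, config$tau), G, S,
                dimnames = list(prot_ids, subjects))
    A <- as.numeric(arm == "treatment")

    sample_ids <- c(paste0(subjects, "_pre"), paste0(subjects, "_post"))
    P <- rep(c(0, 1), each = S)
    mean_mat <- matrix(0, G, 2L * S)
    for (j in seq_len(2L * S)) {
        s <- (j - 1L) %% S + 1L
        mean_mat[, j] <- mu + u[, s] + beta_g * A[s] + gamma_g * P[j] +
            delta_g * A[s] * P[j]
    }
    eps <- matrix(rnorm(G * 2L * S, 0, config$sigma), G, 2L * S)
    m <- mean_mat + eps
    dimnames(m) <- list(prot_ids, sample_ids)

    samples <- DataFrame(
        sample_id = sample_ids,
        subject_id = rep(subjects, 2L),
        arm = rep(arm, 2L),
        timepoint = rep(TIMEPOINT_LEVELS, each = S),
        sex = rep(rep(c("male", "female"), length.out = S), 2L),
        age = rep(round(runif(S, 45, 85)), 2L))
    proteins <- DataFrame(assay_id = prot_ids, gene_symbol = toupper(prot_ids))
    x <- NPXExperiment(m, proteins = proteins, samples = samples)
    truth <- new("SimulationTruth",
                 proteins = DataFrame(assay_id = prot_ids, class = cls,
                                      mu = mu, delta = delta_g,
                                      gamma = gamma_g, beta = beta_g),
                 subjectEffects = u, seed = config$seed)
    validObject(truth)
    list(experiment = x, truth = truth)
}

#' Attach simulated clinical scores to a cohort
#'
#' Generates integer NIHSS (0-42) and ESRS (0-9) scores linearly coupled to
#' chosen proteins: score_st = round(clip(a0 + sum_g w_g NPX_gst + noise)),
#' clipped to the scale range, computed at both timepoints. Negative weights
#' therefore yield negative protein-score correlations by construction. Score
#' noise uses its own stream, seeded deterministically from `config$seed`
#' (seed + 1), so scores can be re-generated without re-simulating NPX.
#'
#' When `config$scoreWeights` is `NULL`, defaults are chosen from the truth:
#' NIHSS takes weight -0.8 on the first three treatment-specific proteins and
#' ESRS -0.25 on the first two (falling back to the first panel proteins if
#' no treatment-specific protein exists).
#'
#' @param x an [NPXExperiment-class] (typically from [simulateCohort()]).
#' @param truth the matching [SimulationTruth-class] (used only to pick
#'   default weight carriers; may be `NULL` when weights are given).
#' @param config the `SimulationConfig`.
#' @return `x` with `nihss` and `esrs` columns filled in `colData`.
#' @export
simulateScores <- function(x, truth, config) {
    stopifnot(is(x, "NPXExperiment"), inherits(config, "SimulationConfig"))
    w <- config$scoreWeights
    if (is.null(w)) {
        if (is.null(truth))
            stop("scoreWeights is NULL and no truth given to pick defaults")
        tr <- truthTable(truth)
        carriers <- tr$assay_id[tr$class == "treatment_specific"]
        if (!length(carriers)) carriers <- tr$assay_id
        w <- list(
            nihss = stats::setNames(rep(-0.8, min(3L, length(carriers))),
                                    utils::head(carriers, 3L)),
            esrs = stats::setNames(rep(-0.25, min(2L, length(carriers))),
                                   utils::head(carriers, 2L)))
    }
    for (sc in names(w)) {
        missing_prot <- setdiff(names(w[[sc]]), assayIds(x))
        if (length(missing_prot))
            stop("scoreWeights for ", sc, " reference unknown protein(s): ",
                 paste(missing_prot, collapse = ", "))
    }
    m <- npxValues(x)
    set.seed(config$seed + 1L)
    mkScore <- function(which, lo, hi) {
        ww <- w[[which]]
        lin <- if (length(ww))
            drop(crossprod(m[names(ww), , drop = FALSE], ww)) else
            rep(0, ncol(m))
        raw <- config$scoreIntercept[[which]] + lin +
            rnorm(ncol(m), 0, config$scoreNoise[[which]])
        as.integer(round(pmin(pmax(raw, lo), hi)))
    }
    cd <- colData(x)
    cd$nihss <- mkScore("nihss", 0, 42)
    cd$esrs <- mkScore("esrs", 0, 9)
    colData(x) <- cd
    validObject(x)
    x
}
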