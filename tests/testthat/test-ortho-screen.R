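test_that("contrast specifications encode the six comparisons", {
    sp <- contrastSpecs()
    expect_equal(names(sp), c("G1", "G2", "G3", "G4", "P1", "P2"))
    expect_equal(sp$G1$groups, c("T2", "C1"))
    expect_equal(sp$G2$groups, c("C2", "T1"))
    expect_equal(sp$G3$groups, c("T1", "C1"))
    expect_equal(sp$G4$groups, c("T2", "C2"))
    expect_true(sp$P1$paired && sp$P1$arm == "treatment")
    expect_true(sp$P2$paired && sp$P2$arm == "control")
    expect_false(any(vapply(sp[1:4], `[[`, logical(1), "paired")))
})

test_that("planted treatment effects carry the right sign in G4 and P1", {
    cfg <- simulationConfig(nTreatment = 12, nControl = 12, nProteins = 8,
                            classCounts = c(treatment_specific = 4,
                                            null = 4),
                            delta = 1.5, sigma = 0.2, tau = 0.3,
                            seed = 21)
    sim <- simulateCohort(cfg)
    d <- validateDesign(sim$experiment)
    res <- runContrasts(sim$experiment, d, contrasts = c("G4", "P1"))
    tr <- truthTable(sim$truth)
    carriers <- tr$assay_id[tr$class == "treatment_specific"]
    for (nm in c("G4", "P1")) {
        r <- res[[nm]]
        b <- r$beta_hat[match(carriers, r$assay_id)]
        expect_equal(sign(b), sign(tr$delta[match(carriers, tr$assay_id)]))
    }
})

test_that("a missing study group aborts the contrasts", {
    x <- makeTinyExperiment(nPerArm = 3, fill = rnorm(36))
    keep <- SummarizedExperiment::colData(x)$sample_id != "c1_post"
    x2 <- as(x[, keep], "NPXExperiment")
    cd <- SummarizedExperiment::colData(x2)
    drop_all_c2 <- !(cd$arm == "control" & cd$timepoint == "post")
    x2 <- as(x2[, drop_all_c2], "NPXExperiment")
    expect_error(validateDesign(x2), "C2")
})

test_that("screening set algebra reproduces the worked cardinalities", {
    # memberships arranged so |set1| = 24, |set2| = 14, |set3| = 45,
    # |set1 n set2| = 5, |set1 n set3| = 16 -> |set4| = 19, |set5| = 16
    prot <- sprintf("g%03d", 1:92)
    mk <- function(sig_set, null_g3 = NULL) {
        p <- ifelse(prot %in% sig_set, 0.01, 0.5)
        if (!is.null(null_g3)) p <- ifelse(prot %in% null_g3, 0.5, 0.01)
        data.frame(assay_id = prot, beta_hat = 1, t_mod = 1, df_total = 10,
                   p = p, q = p)
    }
    set1_members <- prot[1:24]
    set2_members <- c(prot[20:24], prot[70:78])        # overlap with set1 = 5
    set3_members <- c(prot[1:16], prot[45:73])         # overlap with set1 = 16
    results <- list(
        G3 = mk(character(), null_g3 = prot),          # all baseline-null
        G4 = mk(set1_members),
        P2 = mk(set2_members),
        P1 = mk(set3_members))
    sets <- buildScreenSets(results, analysisConfig())
    expect_length(screenSet(sets, "set1"), 24)
    expect_length(screenSet(sets, "set2"), 14)
    expect_length(screenSet(sets, "set3"), 45)
    expect_length(screenSet(sets, "set4"), 19)
    expect_length(screenSet(sets, "set5"), 16)
    expect_equal(screenSet(sets, "core"),
                 setdiff(intersect(set1_members, set3_members),
                         set2_members))
    expect_error(buildScreenSets(results[c("G3", "G4")], analysisConfig()),
                 "missing contrast")
})

test_that("empty set1 collapses sets 4, 5 and the core", {
    prot <- c("a", "b")
    mk <- function(p) data.frame(assay_id = prot, beta_hat = 1, t_mod = 1,
                                 df_total = 10, p = p, q = p)
    results <- list(G3 = mk(0.01), G4 = mk(0.5), P2 = mk(0.5),
                    P1 = mk(0.01))
    sets <- buildScreenSets(results, analysisConfig())
    expect_length(screenSet(sets, "set1"), 0)
    expect_length(screenSet(sets, "set4"), 0)
    expect_length(screenSet(sets, "set5"), 0)
    expect_length(screenSet(sets, "core"), 0)
})

test_that("core identity holds on random membership configurations", {
    set.seed(99)
    prot <- sprintf("g%02d", 1:30)
    for (i in 1:1000) {
        mk <- function() data.frame(assay_id = prot, beta_hat = 1,
                                    t_mod = 1, df_total = 10,
                                    p = sample(c(0.01, 0.5), 30, TRUE),
                                    q = NA)
        results <- list(G3 = mk(), G4 = mk(), P2 = mk(), P1 = mk())
        sets <- buildScreenSets(results, analysisConfig())
        expect_setequal(screenSet(sets, "core"),
                        setdiff(intersect(screenSet(sets, "set1"),
                                          screenSet(sets, "set3")),
                                screenSet(sets, "set2")))
        expect_gte(length(screenSet(sets, "set5")),
                   length(screenSet(sets, "core")))
        expect_true(all(screenSet(sets, "set4") %in% screenSet(sets, "set1")))
    }
})

test_that("p exactly at alpha is neither significant nor baseline-null-eligible", {
    prot <- c("tie_g3", "tie_g4", "clean")
    mk <- function(p) data.frame(assay_id = prot, beta_hat = 1, t_mod = 1,
                                 df_total = 10, p = p, q = NA)
    results <- list(G3 = mk(c(0.05, 0.5, 0.5)),
                    G4 = mk(c(0.01, 0.05, 0.01)),
                    P2 = mk(c(0.5, 0.5, 0.5)),
                    P1 = mk(c(0.01, 0.01, 0.01)))
    expect_message(sets <- buildScreenSets(results, analysisConfig()),
                   "exactly at alpha")
    # tie_g3: G3 p == alpha -> not null-eligible; tie_g4: G4 p == alpha ->
    # not significant; only "clean" makes set1
    expect_equal(screenSet(sets, "set1"), "clean")
})

test_that("core membership is not monotone in alpha", {
    # protein in the core at alpha = 0.05 but not at 0.01: its P2 p-value
    # sits between the two thresholds... the reverse: a protein excluded at
    # 0.05 because of set2 membership re-enters the core when alpha drops
    # below its P2 p-value.
    prot <- "g"
    mk <- function(p) data.frame(assay_id = prot, beta_hat = 1, t_mod = 1,
                                 df_total = 10, p = p, q = NA)
    results <- list(G3 = mk(0.9), G4 = mk(0.001), P2 = mk(0.03),
                    P1 = mk(0.001))
    core_at <- function(alpha) screenSet(
        buildScreenSets(results, analysisConfig(alpha = alpha)), "core")
    expect_length(core_at(0.05), 0)   # excluded via set2
    expect_equal(core_at(0.01), "g")  # set2 loses it; core gains it
})

test_that("screen recovers planted classes on a separable cohort", {
    cfg <- simulationConfig(nTreatment = 16, nControl = 16, nProteins = 30,
                            classCounts = c(treatment_specific = 8,
                                            time_dependent = 8, mixed = 4,
                                            null = 10),
                            delta = 3, gamma = -2.5, sigma = 0.15,
                            tau = 0.2, seed = 31)
    sim <- simulateCohort(cfg)
    d <- validateDesign(sim$experiment)
    sets <- buildScreenSets(runContrasts(sim$experiment, d), analysisConfig())
    rec <- evaluateRecovery(sets, sim$truth)
    # a carrier can still flunk the baseline-null G3 criterion with type-I
    # probability alpha, so sensitivity is high but not guaranteed to be 1
    expect_gte(rec$sensitivity, 0.75)
    expect_equal(rec$leakage_time_dependent, 0)
    expect_equal(rec$leakage_mixed, 0)
    expect_error(
        evaluateRecovery(sets, simulateCohort(simulationConfig(
            nProteins = 5, nTreatment = 2, nControl = 2,
            classCounts = c(null = 5)))$truth),
        "absent from truth")
})
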