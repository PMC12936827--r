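test_that("ordinary statistics match hand-computed values", {
    # paired: within-subject differences 1.0, 1.2, 0.8, 1.0
    pre <- c(0, 0, 0, 0)
    post <- c(1.0, 1.2, 0.8, 1.0)
    x <- makeTinyExperiment(nProteins = 1, nPerArm = 4,
                            values = matrix(c(pre, rep(0, 4), post,
                                              rep(0, 4)), 1, 16))
    d <- validateDesign(x)
    st <- ordinaryStats(x, d, contrastSpecs()$P1)
    expect_equal(st$beta_hat, 1.0)
    expect_equal(st$s2, 0.08 / 3)
    expect_equal(st$d, 3)
    expect_equal(st$u, 0.5)
    expect_equal(st$n, 4)

    # unpaired identical groups: zero effect and zero pooled variance
    x2 <- makeTinyExperiment(nProteins = 1, nPerArm = 3,
                             values = matrix(rep(c(1, 2, 3), length.out = 12),
                                             1, 12, byrow = TRUE))
    d2 <- validateDesign(x2)
    st2 <- ordinaryStats(x2, d2, contrastSpecs()$G3)
    expect_equal(st2$beta_hat, 0)
    expect_equal(st2$d, 4)
    expect_equal(st2$u, sqrt(2 / 3))
})

test_that("proteins with insufficient complete observations are dropped and logged", {
    x <- makeTinyExperiment(nProteins = 2, nPerArm = 3, fill = 1)
    v <- npxValues(x) + matrix(rnorm(24, sd = 0.1), 2)
    # protein 2: keep exactly one complete treatment pair
    v[2, c("t1_post", "t2_pre")] <- NA
    v[2, "t3_pre"] <- NA; v[2, "t3_post"] <- NA
    SummarizedExperiment::assays(x, withDimnames = FALSE)$npx <- v
    d <- validateDesign(x)
    expect_message(st <- ordinaryStats(x, d, contrastSpecs()$P1), "dropped")
    expect_equal(st$assay_id, "p01")
    expect_equal(names(attr(st, "dropped")), "p02")
})

test_that("prior fit recovers its own generative parameters", {
    # s2_g ~ s0^2 d0 / chisq_d0 scaled by chisq_d sampling noise:
    # draw s2_g | sg2 ~ sg2 * chisq_d / d with sg2 ~ s0^2 d0 / chisq_d0
    set.seed(101)
    G <- 2000; d0 <- 4; s0 <- 1; d <- 40
    sg2 <- s0 * d0 / rchisq(G, d0)
    s2 <- sg2 * rchisq(G, d) / d
    st <- data.frame(assay_id = paste0("g", 1:G), beta_hat = 0, s2 = s2,
                     d = d, u = 1)
    pr <- fitEbayesPrior(st)
    expect_lt(abs(pr$d0 - d0) / d0, 0.2)
    expect_lt(abs(pr$s0_sq - s0) / s0, 0.1)
})

test_that("prior fit agrees with the reference empirical-Bayes implementation", {
    skip_if_not_installed("limma")
    set.seed(7)
    s2 <- exp(rnorm(300, 0, 1))
    d <- rep(20, 300)
    st <- data.frame(assay_id = paste0("g", 1:300), beta_hat = 0, s2 = s2,
                     d = d, u = 1)
    pr <- fitEbayesPrior(st)
    sq <- limma::squeezeVar(s2, df = d)
    expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
    expect_equal(pr$s0_sq, sq$var.prior, tolerance = 1e-6)
    # and the shrunken variances follow
    post <- (pr$d0 * pr$s0_sq + d * s2) / (pr$d0 + d)
    expect_equal(post, sq$var.post, tolerance = 1e-6)
})

test_that("prior fit handles degenerate dispersion and tiny panels", {
    st_eq <- data.frame(assay_id = c("a", "b", "c"), beta_hat = 0,
                        s2 = c(2, 2, 2), d = 10, u = 1)
    pr <- fitEbayesPrior(st_eq)
    expect_identical(pr$d0, Inf)
    # d0 = Inf pins every shrunken variance at s0_sq
    r <- moderatedTest(st_eq, pr)
    expect_equal(r$t_mod, st_eq$beta_hat / (sqrt(pr$s0_sq) * st_eq$u))
    expect_error(fitEbayesPrior(data.frame(assay_id = "a", beta_hat = 0,
                                           s2 = 1, d = 10, u = 1)),
                 "at least 2")
    expect_error(fitEbayesPrior(data.frame(assay_id = c("a", "b"),
                                           beta_hat = 0, s2 = c(0, 0),
                                           d = 10, u = 1)),
                 "zero")
})

test_that("moderated test reduces to the classic t at d0 = 0 and to the normal at d0 = Inf", {
    set.seed(33)
    for (i in 1:500) {
        nA <- sample(3:8, 1); nB <- sample(3:8, 1)
        a <- rnorm(nA, sd = runif(1, 0.5, 2))
        b <- rnorm(nB, sd = runif(1, 0.5, 2))
        st <- data.frame(
            assay_id = "g", beta_hat = mean(a) - mean(b),
            s2 = ((nA - 1) * var(a) + (nB - 1) * var(b)) / (nA + nB - 2),
            d = nA + nB - 2, u = sqrt(1 / nA + 1 / nB))
        r0 <- moderatedTest(st, list(d0 = 0, s0_sq = 1))
        tt <- t.test(a, b, var.equal = TRUE)
        expect_equal(r0$t_mod, unname(tt$statistic), tolerance = 1e-10)
        expect_equal(r0$p, tt$p.value, tolerance = 1e-10)
    }
    # paired flavour against the one-sample t
    set.seed(34)
    for (i in 1:100) {
        D <- rnorm(sample(3:10, 1))
        st <- data.frame(assay_id = "g", beta_hat = mean(D), s2 = var(D),
                         d = length(D) - 1, u = sqrt(1 / length(D)))
        r0 <- moderatedTest(st, list(d0 = 0, s0_sq = 1))
        tt <- t.test(D)
        expect_equal(r0$p, tt$p.value, tolerance = 1e-10)
    }
    rInf <- moderatedTest(data.frame(assay_id = "g", beta_hat = 1, s2 = 5,
                                     d = 3, u = 0.5),
                          list(d0 = Inf, s0_sq = 0.25))
    expect_equal(rInf$t_mod, 1 / (0.5 * 0.5))
    expect_equal(rInf$p, 2 * pnorm(-4))
})

test_that("moderated test agrees with an independent straight-line oracle", {
    st <- data.frame(assay_id = "g", beta_hat = 1.0, s2 = 0.08 / 3, d = 3,
                     u = 0.5)
    r <- moderatedTest(st, list(d0 = 4, s0_sq = 0.05))
    o <- oracleModeratedT(1.0, 0.08 / 3, 3, 0.5, 4, 0.05)
    expect_equal(r$t_mod, o$t, tolerance = 1e-12)
    expect_equal(r$p, o$p, tolerance = 1e-12)
    expect_equal(r$df_total, 7)
    # and on a random batch
    set.seed(55)
    st2 <- data.frame(assay_id = paste0("g", 1:50),
                      beta_hat = rnorm(50), s2 = rchisq(50, 5) / 5,
                      d = sample(3:30, 50, TRUE), u = runif(50, 0.2, 1))
    pr <- fitEbayesPrior(st2)
    r2 <- moderatedTest(st2, pr)
    o2 <- oracleModeratedT(st2$beta_hat, st2$s2, st2$d, st2$u, pr$d0,
                           pr$s0_sq)
    expect_equal(r2$t_mod, o2$t, tolerance = 1e-12)
    expect_equal(r2$p, o2$p, tolerance = 1e-12)
})

test_that("shrinkage is monotone: s2_tilde lies between s2 and s0_sq and moves toward the prior as d0 grows", {
    s2 <- c(0.1, 0.5, 2, 10)
    d <- 5; s0 <- 1
    tilde <- function(d0) (d0 * s0 + d * s2) / (d0 + d)
    for (d0 in c(0.5, 2, 8)) {
        tl <- tilde(d0)
        expect_true(all(tl >= pmin(s2, s0) & tl <= pmax(s2, s0)))
    }
    gaps <- sapply(c(0.5, 2, 8, 32, 128), function(d0) abs(tilde(d0) - s0))
    expect_true(all(apply(gaps, 1, function(z) all(diff(z) <= 1e-12))))
})

test_that("direction labels follow the p-only and p-and-fc rules", {
    res <- data.frame(assay_id = c("a", "b", "c"),
                      beta_hat = c(0.6, 0.3, 2.0),
                      t_mod = 1, df_total = 10,
                      p = c(0.04, 0.04, 0.50), q = NA)
    cfg <- analysisConfig()
    r1 <- classifyDeps(res, cfg, rule = "p_only")
    expect_equal(as.character(r1$direction), c("up", "up", "ns"))
    r2 <- classifyDeps(res, cfg, rule = "p_and_fc")
    expect_equal(as.character(r2$direction), c("up", "ns", "ns"))
    expect_equal(unname(c(attr(r2, "counts"))), c(1L, 0L, 2L))
    # counts are order-invariant and partition the proteins
    perm <- c(3, 1, 2)
    r3 <- classifyDeps(res[perm, ], cfg, rule = "p_and_fc")
    expect_equal(attr(r3, "counts"), attr(r2, "counts"))
    expect_equal(sum(attr(r3, "counts")), nrow(res))
})

test_that("BH adjustment matches a hand step-up oracle", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.2), 0.2)
    expect_equal(bhFdr(c(0.5, 1.0)), c(1.0, 1.0))
    expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
    set.seed(77)
    for (i in 1:1000) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhFdr(p), oracleBh(p))
    }
})

test_that("moderated p-values are uniform under the null", {
    # 2500 null proteins, d = 10, one shared prior
    set.seed(88)
    n <- 6; G <- 2500
    mats <- matrix(rnorm(G * 2 * n), G)
    a <- mats[, 1:n]; b <- mats[, (n + 1):(2 * n)]
    st <- data.frame(
        assay_id = paste0("g", 1:G),
        beta_hat = rowMeans(a) - rowMeans(b),
        s2 = (apply(a, 1, var) * (n - 1) + apply(b, 1, var) * (n - 1)) /
            (2 * n - 2),
        d = 2 * n - 2, u = sqrt(2 / n))
    r <- moderatedTest(st, fitEbayesPrior(st))
    frac <- mean(r$p < 0.05)
    band <- qbinom(c(0.005, 0.995), G, 0.05) / G
    expect_gte(frac, band[1])
    expect_lte(frac, band[2])
})
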