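# Shared fixtures, all built in code at test time.

# A minimal experiment: nProteins x (2 arms x nPerArm subjects x 2 timepoints),
# values filled from `fill` (recycled) unless a matrix is given.
makeTinyExperiment <- function(nProteins = 3, nPerArm = 3, fill = 0,
                               values = NULL, sex = NULL) {
    subjects <- c(sprintf("t%d", seq_len(nPerArm)),
                  sprintf("c%d", seq_len(nPerArm)))
    arm <- rep(c("treatment", "control"), each = nPerArm)
    ann <- data.frame(
        sample_id = c(paste0(subjects, "_pre"), paste0(subjects, "_post")),
        subject_id = rep(subjects, 2),
        arm = rep(arm, 2),
        timepoint = rep(c("baseline", "post"), each = 2 * nPerArm),
        stringsAsFactors = FALSE)
    if (!is.null(sex)) ann$sex <- rep(sex, 2)
    if (is.null(values))
        values <- matrix(fill, nProteins, nrow(ann))
    rownames(values) <- sprintf("p%02d", seq_len(nProteins))
    colnames(values) <- ann$sample_id
    NPXExperiment(values, samples = ann)
}

# Write a long NPX file + annotation file for a small cell table.
writeLongFixture <- function(dir, rows, ann, sep = ",") {
    ext <- if (sep == "\t") ".tsv" else ".csv"
    npx_path <- file.path(dir, paste0("npx", ext))
    ann_path <- file.path(dir, paste0("ann", ext))
    write.table(rows, npx_path, sep = sep, row.names = FALSE, quote = FALSE)
    write.table(ann, ann_path, sep = sep, row.names = FALSE, quote = FALSE)
    list(npx = npx_path, ann = ann_path)
}

tinyAnnotation <- function() {
    data.frame(sample_id = c("s1", "s2"),
               subject_id = c("u1", "u2"),
               arm = c("treatment", "control"),
               timepoint = c("baseline", "baseline"),
               stringsAsFactors = FALSE)
}

# Independent straight-line re-implementation of the moderated test used as
# a dual-implementation oracle (kept free of package internals on purpose).
oracleModeratedT <- function(beta_hat, s2, d, u, d0, s0_sq) {
    s2_tilde <- (d0 * s0_sq + d * s2) / (d0 + d)
    t_mod <- beta_hat / (sqrt(s2_tilde) * u)
    list(t = t_mod, p = 2 * stats::pt(-abs(t_mod), d0 + d))
}

# Hand step-up BH oracle.
oracleBh <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
}

# Brute-force Spearman: average ranks then Pearson.
oracleSpearman <- function(x, y) {
    stats::cor(rank(x), rank(y), method = "pearson")
}

# Exact hypergeometric upper tail by direct combinatorial count.
oracleHyperUpper <- function(k, K, n, N) {
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
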