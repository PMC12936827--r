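---
title: "Methods: moderated contrasts and triple orthogonal screening for NPX trial data"
author: "orthoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated contrasts and triple orthogonal screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscreen)
```

# The problem

A two-arm randomized trial measures a targeted protein panel (Olink-style
NPX values, an arbitrary unit on a log2 scale) in every subject at baseline
and after the intervention period. Four cells result: treatment baseline
(T1), treatment post (T2), control baseline (C1), control post (C2). Three
things can move a protein between baseline and follow-up: the treatment, the
natural time course of the disease, and baseline heterogeneity left by
randomization at small n. The package's job is to separate the first from
the other two, for every protein at once, and to verify that the separation
actually works — on synthetic cohorts where the truth is known.

# The moderated contrast engine

## Ordinary statistics

Each contrast reduces to a per-protein effect estimate with a residual
variance:

* **Unpaired** (one cell vs another): effect `b = mean(A) − mean(B)`,
  pooled variance `s²`, residual df `d = nA + nB − 2`, unscaled standard
  error `u = sqrt(1/nA + 1/nB)`.
* **Paired** (post vs pre within one arm): per-subject differences
  `D = post − pre` over complete pairs; `b = mean(D)`, `s² = var(D)`,
  `d = n − 1`, `u = sqrt(1/n)`.

Because NPX is already log2-scale, `b` *is* the log2 fold change; no
re-exponentiation happens anywhere. Missing values are never imputed: a
protein contributes only its complete observations (complete pairs for
paired contrasts), and proteins with fewer than two observations per group
(or two complete pairs) are dropped from that contrast with a logged reason.

The `pairedModel` setting accepts `"difference"` and `"blocked"`. For the
balanced complete pairs that are the only data admitted into paired
contrasts, the one-sample t on within-subject differences and the
subject-blocked two-way OLS model are the same statistic (identical
estimate, residual variance and df), so both settings run the same
computation; the test suite asserts the equivalence against `lm()` with a
subject factor.

## Empirical-Bayes moderation

With 92 proteins and ~22 subjects per cell, per-protein variance estimates
are noisy. The engine therefore shrinks them toward a panel-wide prior
before testing, using the standard hierarchical model in which the true
variances follow a scaled inverse-chi-square law with prior df `d0` and
prior variance `s0²`. The prior is fitted per contrast by method of moments
on `z = log s²`:

* `e_g = z_g − digamma(d_g/2) + log(d_g/2)` has mean `log σ²_g`-ish and a
  known sampling variance `trigamma(d_g/2)`;
* the excess of the observed dispersion of `e` over that sampling variance
  estimates `trigamma(d0/2)`, inverted numerically (Newton on the inverse
  trigamma, 1e-10 relative tolerance);
* `s0² = exp(ē + digamma(d0/2) − log(d0/2))`.

If the excess dispersion is non-positive the prior is degenerate:
`d0 = ∞`, every protein gets `s̃² = s0² = exp(ē)`, and the reference
distribution is standard normal. Otherwise
`s̃² = (d0·s0² + d·s²)/(d0 + d)` and `t = b/(s̃·u)` is referred to Student's
t with `d0 + d` df. At `d0 = 0` this collapses to the classic t-test — the
test suite holds the implementation to that limit at 1e-10, and to the
reference empirical-Bayes implementation in `limma::squeezeVar` at 1e-6.

One prior is fitted per contrast, not globally: unpaired and paired
contrasts have different residual structures (subject effects cancel in
differences), so pooling their variances would bias `d0`.

Proteins with `s² = 0` (constant values) are excluded from the moment
equations (their log-variance is undefined) but still tested: shrinkage
gives them a positive `s̃²`, where a classic t would be 0/0.

# The six contrasts and the screen

Six contrasts cover the design: G1 (T2 vs C1), G2 (C2 vs T1), G3 (T1 vs
C1), G4 (T2 vs C2) unpaired, and P1 (T2 vs T1, treatment arm), P2 (C2 vs
C1, control arm) paired. Effects are oriented toward the first-named group.
G1 and G2 are descriptive only; inference rests on G3, G4, P1 and P2.

The screen is set algebra over significance calls at level `alpha`
(default 0.05):

| set | definition | reads as |
|-----|------------|----------|
| set1 | G3 p > α **and** G4 significant | diverged after intervention without baseline imbalance |
| set2 | P2 significant | time-dependent (moves in the control arm) |
| set3 | P1 significant | treatment-responsive |
| set4 | set1 \\ set2 | set1 minus time-dependent proteins |
| set5 | set1 ∩ set3 | inter-group and longitudinal agreement |
| core | set3 ∩ set4 ∩ set5 | treatment-specific candidates |

The definition implies the identity `core = (set1 ∩ set3) \\ set2`, which
the `ScreenSets` validity method enforces on every object and the test
suite checks on 1000 random membership configurations. It also implies
`|set5| ≥ |core|`.

Decisions where the procedure was genuinely open:

* **Ties at alpha.** Strict inequalities both ways: `p < α` for
  significance, `p > α` for baseline-null eligibility. A p exactly at α is
  neither, and a message is logged when one occurs.
* **Membership rule.** `p_only` (default) calls significance on the
  p-value alone; `p_and_fc` additionally requires `|log2FC| > fcCut`
  (default 0.5), the volcano-labeling convention. The two rules can give
  different DEP counts and set sizes; the pipeline reports both side by
  side in `summary.json` because targeted-panel reports are often ambiguous
  about which was used.
* **Dropped proteins.** A protein dropped from any of G3/G4/P1/P2 leaves
  the screening universe entirely (with a manifest), rather than being
  treated as non-significant.
* **Monotonicity.** Lowering α shrinks each significance set, but the core
  is *not* monotone in α: a protein excluded through set2 can re-enter the
  core when α drops below its P2 p-value. A constructed example in the test
  suite demonstrates this.

# The synthetic cohort generator

`simulateCohort()` draws, for protein g, subject s (treatment indicator A)
and timepoint (post indicator P):

```
NPX = mu_g + u_gs + beta_g·A + gamma_g·P + delta_g·A·P + eps
u_gs ~ N(0, tau²)   shared by a subject's two samples
eps  ~ N(0, sigma²)
```

Each protein belongs to one class: `null` (no effects),
`treatment_specific` (δ only), `time_dependent` (γ only),
`baseline_shifted` (β only), or `mixed` (γ and δ — planted specifically to
verify that the set2 exclusion removes proteins whose change is partly
time-driven). Effect magnitudes default to δ = 1.0, γ = −0.8, β = 0.7 NPX
units with per-protein random signs; noise to τ = 0.5 (subject) and
σ = 0.4 (residual) NPX units; baseline means uniform on [2, 10] NPX. The
default panel is 92 proteins — 10 treatment-specific, 10 time-dependent,
5 mixed, 67 null — over 22 + 22 subjects, matching the scale of the kind of
pilot trial the pipeline targets. The deposited data report no usable
effect-size estimates, so the magnitudes are chosen to be clearly
recoverable at that scale (roughly 2–2.5 residual Sds) while leaving the
baseline-null G3 criterion a real hurdle; they are configuration, not
claims about any study.

Clinical scores are generated as
`round(clip(a0 + Σ w_g·NPX_g + noise))` — NIHSS clipped to [0, 42], ESRS
to [0, 9], at both timepoints. Default weights are negative (−0.8 on three
treatment-specific proteins for NIHSS, −0.25 on two for ESRS), so proteins
the treatment raises correlate negatively with severity, mirroring the
pattern the correlation stage is meant to detect. Rounding happens after
noise, matching integer scales.

All randomness comes from one generator seeded with `config$seed`, drawn in
a fixed order (baseline means, effect signs, subject effects, residuals);
scores use a stream derived from the same seed. Identical configs are
bit-identical.

What the generator does **not** emulate: limit-of-detection censoring,
plate/batch effects, non-Gaussian tails, correlated proteins, dropout, and
time-varying clinical scores beyond their protein coupling. Passing
recovery tests therefore demonstrates that the screen's logic does what it
claims under its own assumptions — not that those assumptions hold in any
particular real dataset.

A subtlety the recovery tests respect: a treatment-specific protein can
still flunk the screen by tripping the baseline G3 criterion, which for it
is a pure null test — that happens with probability ≈ α per protein
regardless of noise levels. Expected sensitivity at defaults is therefore
about `(1 − α)² ≈ 0.90` (G3 and P2 must both stay quiet), not 1. The
acceptance suite asserts mean sensitivity ≥ 0.8 and time-dependent leakage
≤ 0.05 over 50 replicate cohorts.

# Downstream stages

* **Clinical correlation.** Spearman rho with average-rank ties; p from the
  t-approximation on n − 2 df; records with fewer than 3 usable pairs or a
  constant variable are NA and never significant. The default scope pools
  the treatment arm's baseline and post samples into one correlation, so
  each subject contributes two observations treated as independent — that
  appears to be the convention of the reports this pipeline emulates and is
  exposed as a choice (`per_timepoint` is the alternative), not endorsed as
  inference. ESRS is handled symmetrically even though it is effectively
  time-constant per subject.
* **Sex comparison.** Two-sided Mann-Whitney per protein (robust at the
  4–18 per-sex counts typical of pilot trials; Welch's t by option), BH
  across the panel, significance at q < 0.05.
* **Importance ranking.** A random forest (the `randomForest` package, 500
  trees, `floor(sqrt(p))` candidates per split, out-of-bag evaluation)
  classifies treatment-arm samples pre vs post from the P1 DEPs and ranks
  them by out-of-bag permutation importance (mean decrease in accuracy) and
  impurity reduction (mean decrease in Gini). The classification target is
  config-selectable (`timepoint` default, `arm` alternative) because the
  emulated analyses leave it unstated. Rankings are seed-deterministic;
  ties break by feature order, documented here.
* **Enrichment.** Hypergeometric upper tail `P(X ≥ k)` per GMT term. The
  urn is annotation-restricted by default (background = panel proteins
  carrying ≥ 1 annotation), which keeps N interpretable; full-panel
  counting is an option. Venn membership uses raw p < α (q is always
  reported alongside); term collections are user-supplied files, since term
  counts depend entirely on annotation versions.

# Numerical choices and degenerate inputs

* Inverse trigamma by Newton iteration (50 iterations max, 1e-10 relative
  tolerance), with asymptotic branches for extreme arguments.
* `|rho| = 1` in the Spearman t-approximation returns p = 0 rather than
  dividing by zero.
* BH uses `stats::p.adjust`; the hypergeometric tail uses `stats::phyper`;
  both are held to hand-rolled oracles in the tests.
* Empty study cells, subjects in both arms, duplicate long-format rows,
  samples missing from annotations, and unparseable arm/timepoint labels
  are hard errors at ingestion, before any statistics run.

# Problem sizes in the verification suite

The test and acceptance runs use the study-scale default (92 proteins,
22 + 22 subjects): 200 pure-null replicate cohorts for type-I calibration,
50 replicates for screen recovery, 20 draws of G = 2000 variances for prior
recovery, 1000 random membership configurations for the set identity, and
20 seeded forests for the separator check. These sizes give Monte-Carlo
standard errors comfortably below the asserted margins while keeping a full
run in the low minutes on one core.

# Limitations

* The screen is a sequence of threshold decisions, not a joint model; it
  controls no family-wise or false-discovery rate across the panel, and its
  output is a candidate list, not a set of confirmed effects.
* Pooled-timepoint correlations double-count subjects; treat the
  significance flags as descriptive.
* The moderation model assumes exchangeable variances across proteins
  within a contrast; strongly intensity-dependent variance would call for a
  trended prior, which is out of scope.
* Covariate adjustment (age, sex) in the contrasts is out of scope; the
  sex-stratified comparison is a marginal check, not an adjustment.
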