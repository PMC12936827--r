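# orthoscreen

Differential-expression analysis and treatment-specificity screening for
targeted proteomics (Olink-style NPX) from two-arm, two-timepoint
randomized trials.

## The problem

A small randomized trial measures a fixed protein panel in every subject
before and after an intervention, giving four cells: treatment baseline
(T1), treatment post (T2), control baseline (C1), control post (C2). A
protein can change because of the treatment — but also because the disease
evolves over the observation window, or because randomization at n ≈ 22 per
arm left baseline imbalance. `orthoscreen` implements the full analysis
chain that separates these explanations:

1. **Six moderated contrasts.** Four unpaired (G1: T2 vs C1, G2: C2 vs T1,
   G3: T1 vs C1, G4: T2 vs C2) and two paired within-arm (P1: T2 vs T1,
   P2: C2 vs C1). Each uses an empirical-Bayes moderated t-statistic: the
   per-protein residual variance s² is shrunk toward a panel-wide prior,
   s̃² = (d₀s₀² + d·s²)/(d₀ + d), and t = β̂/(s̃·u) is referred to Student's
   t with d₀ + d df. The prior (d₀, s₀²) is fitted per contrast by method
   of moments on log s². NPX is log2-scale, so β̂ is the log2 fold change
   directly.
2. **Triple orthogonal screening.** Set algebra over the contrast calls at
   level α: set1 = {no baseline difference (G3 p > α), post-intervention
   difference (G4 p < α)}; set2 = {P2 p < α} (time-dependent);
   set3 = {P1 p < α} (treatment-responsive); set4 = set1 \ set2;
   set5 = set1 ∩ set3; **core** = set3 ∩ set4 ∩ set5 = (set1 ∩ set3) \ set2
   — the treatment-specific candidates.
3. **Downstream stages.** Spearman correlation of proteins with clinical
   scores (NIHSS, ESRS) and overlap with the core; sex-stratified
   Mann-Whitney comparisons with BH-FDR; random-forest importance ranking
   (mean decrease in accuracy / Gini) of the P1 DEPs; hypergeometric
   over-representation analysis against user-supplied GMT collections.
4. **A synthetic-cohort generator** with planted effect classes
   (treatment-specific, time-dependent, baseline-shifted, mixed, null) and
   full ground truth, so the whole pipeline is verifiable by parameter
   recovery without any external data.

Data live in an `NPXExperiment` (a `SummarizedExperiment` with an `npx`
assay, protein annotation in `rowData`, study annotation in `colData`),
built from standard long-format NPX + annotation tables by `readNpxLong()`.

## Worked example

```r
library(orthoscreen)

sim    <- simulateCohort(simulationConfig(seed = 7))
x      <- simulateScores(sim$experiment, sim$truth, simulationConfig(seed = 7))
design <- validateDesign(x)
design
#> StudyDesign: T1 = 22  T2 = 22  C1 = 22  C2 = 22
#>   paired subjects: treatment = 22 , control = 22

contrasts <- runContrasts(x, design)
head(contrasts$P1[order(contrasts$P1$p), ], 3)
#>    assay_id  beta_hat      t_mod df_total            p            q direction
#> 70  prot070 -1.241073 -10.209392 341.1383 1.571045e-21 1.445361e-19      down
#> 76  prot076 -1.123265  -9.085222 341.1383 8.580233e-18 2.673434e-16      down
#> 69  prot069 -1.103332  -9.083075 341.1383 8.717718e-18 2.673434e-16      down

sets <- buildScreenSets(contrasts)
sets
#> ScreenSets (alpha = 0.05 , rule = p_only )
#>   set1  n = 18
#>   set2  n = 17
#>   set3  n = 23
#>   set4  n = 13
#>   set5  n = 10
#>   core  n = 9
#>   universe: 92 proteins

evaluateRecovery(sets, sim$truth)[c("sensitivity", "leakage_time_dependent")]
#> $sensitivity
#> [1] 0.9
#> $leakage_time_dependent
#> [1] 0

corr <- spearmanScores(x, design, "nihss")
overlapWithCore(corr, sets)
#> $proteins
#> [1] "prot070" "prot073" "prot071" "prot075" "prot076"
#> $count
#> [1] 5
```

Reading the output: `beta_hat` is the log2FC of the paired post-vs-pre
contrast in the treatment arm (negative here because this cohort's planted
effect signs happen to be negative for these proteins); `df_total` is the
moderated degrees of freedom d₀ + d. Of this cohort's 10 planted
treatment-specific proteins the screen's core recovered 9 (one tripped the
baseline G3 criterion, a type-I event with probability ≈ α per protein,
which is why expected sensitivity is ≈ (1 − α)² ≈ 0.90 rather than 1), and
none of the 10 time-dependent proteins leaked in. Five core proteins also
correlate significantly with the simulated NIHSS score — the generator
couples NIHSS to three treatment-specific proteins with negative weights.

`runPipeline()` runs the same chain from a YAML/list config (real files or
a simulation block) and writes per-contrast TSVs, `screen_sets.tsv`,
`correlations.tsv`, `importance.tsv`, enrichment tables, `summary.json`
(DEP counts and set sizes under both membership rules) and a
`manifest.json` with digests. A thin CLI over it lives at
`inst/scripts/orthoscreen.R` (verbs `simulate`, `run`, `replicate`);
`replicateStudy()` recomputes DEP counts and set cardinalities from a
locally downloaded copy of the deposited trial data
(doi:10.5281/zenodo.16551369) and prints them next to the reported counts
under both membership rules.

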