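# sigstep

Step-threshold scoring of gene-expression signatures, with the downstream
statistics that usually travel with it: two-group classification, signature
derivation by differential expression, protein-network hub analysis, and
survival stratification.

## The problem

Given a gene signature — a set of genes expected high (up) or low (down) in
some biological state — and a genes × samples expression matrix, how strongly
does each sample express that state, and does the resulting score separate
known groups or predict outcome? `sigstep` answers this with a composite
score built on a step-function view of each gene:

1. **Step threshold.** Each gene's values are sorted and a one-step function
   is fitted by scanning every split `k` and minimizing the squared error;
   the fit quality is

   `F = [Σ(X̂ᵢ − X̄)² / (m − 1)] / [Σ(Xᵢ − X̂ᵢ)² / (n − m)]`,  `m = 3`,

   and the binarization threshold is the midpoint of the two segment means,
   `SThr = (μ_L + μ_R) / 2`.

2. **Modified Z-score.** Each value is centered on its gene's threshold and
   scaled by three standard deviations: `z = (x − SThr) / (3σ)`.

3. **Composite score.** Per sample, `score = Σ z(up genes) − Σ z(down genes)`
   (a plain all-genes sum is available as `mode = "sum_all"`).

4. **Separation statistics.** ROC-AUC in the Mann–Whitney rank form (ties
   counted ½) plus Welch's two-sample t-test on the scores.

Around this core: `per_gene_test()` + `filter_degs()` derive a signature
from a two-group comparison (Welch per gene, Benjamini–Hochberg adjustment,
`|logFC|`/`padj` cuts), `overrepresentation()` runs hypergeometric
enrichment against GMT gene sets, `build_graph()`/`degree_zscores()`/
`select_hubs()` find hubs in a PPI edge list by degree z-score
(`Z_d = (deg − mean)/sd_pop`), and `stratify_by_score()` +
`km_estimate()`/`logrank()` split a cohort at the step threshold of the
composite score and compare survival. A seeded generator
(`simulate_expression()`, `simulate_survival()`, `simulate_graph()`) makes
every stage testable without downloads.

## Worked example

```r
library(sigstep)

# a fitted step on a near-perfect series
fit_step(c(1.1, 0.9, 1.0, 4.8, 5.2, 5.0))
#> <step_fit> n = 6, k = 3, means 1 -> 5, sthr = 3, sse = 0.1

# simulate the reference conditions: 29 up / 3 down signature, effect 2,
# noise 0.5, 20 samples per group
sim <- simulate_expression(sim_config(seed = 42))
report <- score_and_classify(sim$matrix, sim$signature, "condition",
                             positive = "autonomous")
report
#> <score_report> 'planted' (32 genes, signed mode)
#>   autonomous (n=20, positive) vs control (n=20) on `condition`
#>   ROC-AUC = 1.000 (up), Welch t = 80.467 (df 32.8), p = 3.01e-39
```

The AUC of 1.0 says every autonomous sample outscores every control sample;
the Welch p-value tests the score difference in location. `tidy(report)`
gives the per-sample scores (sorted ascending), `glance(report)` the one-row
summary, `autoplot(report)` a violin plot.

Survival stratification at the step threshold of the score:

```r
surv  <- simulate_survival(tidy(report), seed = 43)
strat <- stratify_by_score(tidy(report), surv)   # splits at sthr = 0.16
logrank(strat)
#> # A tibble: 1 × 3
#>   chisq    df          p
#>   <dbl> <int>      <dbl>
#> 1  23.2     1 0.00000146
```

High-score subjects die faster by construction (the generator ties the
hazard to the score); the log-rank test recovers that at p ≈ 1.5e-6.

The whole chain — simulate, derive the signature by differential
expression, score it, stratify survival, find graph hubs — runs as one
deterministic pipeline:

```r
res <- run_pipeline(synthetic_preset(seed = 7), "run_out/")
```

which writes every intermediate TSV, a log, and a checksum manifest under
`run_out/`. A thin CLI over the same functions lives at
`inst/cli/sigstep.R`.

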