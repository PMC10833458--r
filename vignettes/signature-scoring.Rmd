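---
title: "Step-threshold signature scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-threshold signature scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigstep)
```

## The problem

Bulk and single-cell transcriptomic studies often summarize a biological
state -- stemness, plasticity, growth-factor self-sufficiency -- as a *gene
signature*: a set of genes expected to move up or down together. To compare
such a state across samples one needs a single per-sample number, a way to
ask how well that number separates two known groups, and a way to relate it
to outcome. `sigstep` implements one coherent recipe for all three, built
around a step-function view of each gene.

## The step-function model of a gene

Many genes in a heterogeneous cohort behave approximately bimodally: a
low-expressing mode and a high-expressing mode, with the interesting
information in which mode a sample occupies. Sorting one gene's values
ascending and fitting a one-step function makes that explicit. For a split
after position $k$ of the $n$ sorted values $X_1 \le \dots \le X_n$, the fit
is the left mean $\mu_L = \frac1k\sum_{i \le k} X_i$ and right mean
$\mu_R = \frac1{n-k}\sum_{i>k} X_i$; `fit_step()` scans all $n-1$ splits and
keeps the one minimizing the squared error
$\mathrm{SSE}(k) = \sum_i (X_i - \hat X_i)^2$. The fit quality statistic is

$$ F = \frac{\sum_i (\hat X_i - \bar X)^2 / (m - 1)}
            {\sum_i (X_i - \hat X_i)^2 / (n - m)} $$

with $m = 3$ model degrees of freedom: two segment means plus the step
position. The *step threshold*

$$ S_{thr} = \tfrac12(\mu_L + \mu_R) $$

is the midpoint of the two fitted levels and is the package's per-gene
binarization point: values above it are "high", values below it "low".

Numerical choices worth knowing:

* **Sorting first.** A step function presumes an ordered series; expression
  samples have no inherent order, so `gene_threshold()` always sorts
  ascending. This is the only ordering that makes the threshold a
  well-defined property of the gene rather than of sample arrangement, and
  it makes the threshold invariant under sample permutation.
* **Ties in the split search.** When several splits achieve the same SSE
  (routine for discretized values), the smallest $k$ wins. The comparison
  uses a relative tolerance of $10^{-10}$ times the total sum of squares so
  that mathematically tied splits do not resolve on floating-point rounding.
* **Ties at the threshold.** A value exactly equal to $S_{thr}$ classifies
  *low*, everywhere (binarization and survival stratification alike).
  Deterministic and documented beats arbitrary.
* **Degenerate input.** A constant series has no step: the fit is flagged
  `no_step`, the threshold falls back to the grand mean, and the F statistic
  is undefined. Downstream, constant genes are excluded from scoring with a
  warning rather than contributing spurious zeros.
* **Intermediate band.** `binarize()` takes a `margin`: values within
  `margin` of the threshold become `NA` rather than being forced into a
  mode. The default is 0 (strictly binary); the margin exists because near
  the threshold the high/low call is the least trustworthy part of the data.
* Only the one-step fit is implemented. Multi-step variants exist in the
  wider step-fitting literature but add nothing when the purpose is a
  single high/low threshold.

## From threshold to composite score

A gene's expression in sample $s$ is converted to a modified Z-score
centered on the step threshold:

$$ z_{g,s} = \frac{x_{g,s} - S_{thr,g}}{3\,\sigma_g} $$

where $\sigma_g$ is the gene's sample standard deviation (denominator
$n-1$) across *all* samples of the dataset. Two deliberate readings are
baked in here:

* The scale factor **divides** by $3\sigma_g$. The formula is sometimes
  written ambiguously as "(expr − SThr)/3 × stddev"; multiplying by
  $\sigma_g/3$ would make noisy genes dominate the score, the opposite of
  normalization, so the division reading is used. A sample sitting three
  standard deviations above its gene's threshold scores exactly 1.
* $\sigma_g$ comes from the whole dataset, not per group -- the score must
  be computable for samples whose group is unknown.

The composite score of a signature $G = G_{up} \cup G_{down}$ is the signed
sum

$$ \mathrm{score}(s) = \sum_{g \in G_{up}} z_{g,s} - \sum_{g \in G_{down}} z_{g,s}, $$

so down-regulated genes pull the score down (mode `"signed"`, the default).
Mode `"sum_all"` adds every gene with weight $+1$, preserving the plain
summed-score variant for comparison studies. Genes absent from a dataset are
dropped with a logged list -- imputing them would fabricate signal, and
cross-platform datasets routinely lack a few signature genes.

Group separation is then quantified two ways on the same scores:
**ROC-AUC** in the Mann-Whitney rank form ($U/(n_1 n_0)$, ties counted
half), which is invariant under any monotone rescaling of scores, and
**Welch's t-test** (unpaired, unequal variances, Welch-Satterthwaite
degrees of freedom) for a location p-value. `score_and_classify()` returns
both in a `score_report` with `tidy()`/`glance()`/`autoplot()` methods.

## Deriving a signature from data

`per_gene_test()` performs the simplest defensible two-group test on
log-scale values: per-gene Welch t with log-fold-change as the difference of
group means, followed by Benjamini-Hochberg adjustment. This is a
location test on log expression, not a count model; if raw counts are the
input, `log_cpm()` (counts per million, then $\log_2(x + 1)$) brings them to
the scale the test assumes. `filter_degs()` turns the table into a
signature with the strict default cuts `|logFC| > 5` and `padj < 0.01`,
keeping only extreme, well-supported genes in both directions.

For interpretation, `overrepresentation()` provides database-free
over-representation analysis against user-supplied GMT gene sets: one-sided
upper-tail hypergeometric p per set, BH across sets. The universe defaults
to the genes the data can actually see (all genes in the matrix), not the
genome -- enrichment against genes that were never measurable is biased.

## PPI hubs

`build_graph()` induces an undirected graph on a filtered protein set from
a STRING-style edge list (self-loops dropped, duplicate and reversed edges
merged; isolated proteins retained). The hub statistic is the degree
z-score

$$ Z_d(v) = \frac{\deg(v) - \overline{\deg}}{\mathrm{sd}_{pop}(\deg)} $$

with the population (n-denominator) standard deviation -- the conventional
z-score, and the choice that gives the clean closed-form values on small
graphs (the center of a 4-leaf star has exactly $Z_d = 2$). A
constant-degree graph gets $Z_d = 0$ everywhere by convention.
`select_hubs()` ranks by degree with alphabetical tie-breaks, so the hub
roster is deterministic. Edge confidence scores may be thresholded at load
but are never used as weights: the statistic of interest is degree.
`filter_proteins()` applies inclusive ratio/significance cutoffs
(defaults $\ge 2$ and $\ge 20$) to a quantitative proteomics table first.

## Survival stratification

`stratify_by_score()` reuses the step machinery on the score axis: fit a
step to the sorted composite scores, split the cohort at the threshold into
"high" and "low", then compare the arms with the Kaplan-Meier estimator and
the two-group log-rank test (delegated to the `survival` package; the test
suite checks both against hand product-limit and observed-minus-expected
computations). Tied event and censoring times follow the standard
events-first convention. The module expects one row per subject; collapsing
repeated samples per subject to a single score is the caller's decision, and
mean aggregation is suggested as a utility only, not a claim about the right
summary. Hazard-ratio (Cox) estimation is deliberately out of scope: the
stratified comparison reports a log-rank p, nothing more.

## What the synthetic generator emulates

`simulate_expression()` generates the structure the analysis assumes, as
directly as possible:

* **Signature genes** (defaults: 29 up, 3 down -- the shape of a realistic
  derived signature) sit at a baseline of 4.0 on log2 scale, the midpoint of
  the two background modes, and shift by `effect` (default 2.0 log2 units)
  up or down in the positive group. Group labels are `"control"` /
  `"autonomous"`.
* **Background genes** carry no group information. A `bimodal_frac` subset
  (default 0.3) is split per sample between modes 2.0 and 6.0 -- the step
  structure the threshold estimator expects -- and the rest sit at a
  gene-specific uniform level between the modes.
* Gaussian noise (`noise_sd`, default 0.5) is added everywhere, and all
  values live directly on log2 scale. The generator is Gaussian-on-log by
  design: every downstream stage (step fit, z-score, Welch) consumes log
  values, so the generator targets that level instead of producing counts;
  `log_cpm()` is exercised separately on count fixtures.
* Sample sizes default to 20 + 20, typical of a two-condition cell-line
  comparison with replicates.

`simulate_survival()` draws exponential event times with rate
$h_0 e^{\beta z}$ on the standardized score (defaults $h_0 = 0.1$,
$\beta = 1.5$, exponential censoring at rate 0.02 -- mild, mostly-observed
follow-up). `simulate_graph()` overlays `n_hubs = 3` planted nodes of
target degree 60 on an Erdős–Rényi background (200 nodes, $p = 0.05$, mean
background degree about 10), giving hubs that are unambiguous without being
trivial. All three generators are seeded and byte-reproducible: the same
`sim_config()` always yields identical output.

What the generator does *not* emulate -- and therefore what passing tests do
not establish about real data: library-size and count-overdispersion
effects, correlated gene modules, batch structure, platform differences
between cohorts, informative censoring, and biological graph topology
beyond degree (no clustering, no communities). Results on simulated data
validate the machinery, not the biology.

## Pipeline

`run_pipeline()` chains the stages
(simulate → differential expression → scoring → survival → PPI) in a fixed
dependency order, writing every intermediate as TSV with a header naming
the package version, config hash, and seed, plus a manifest of MD5
checksums. Outputs contain no timestamps, so identical config and seed give
byte-identical runs -- the determinism contract the test suite enforces.
Configuration is a nested YAML/list structure validated by
`validate_config()`: unknown keys are rejected (typo protection), defaults
are filled, and normalization is idempotent.

One preset knob deserves a note: `synthetic_preset()` sets the DEG stage's
`lfc_cut` to 1 rather than the package default of 5, because the planted
effect is 2 log2 units -- a cut of 5 would, by construction, return an empty
signature on simulated data. The default of 5 remains the right choice for
its intended use: isolating a handful of extreme genes from a strong
two-condition contrast.

## Problem sizes used by the checks

The package's own verification (the test suite and
`scripts/acceptance.R`) runs at sizes chosen to make the statistical
assertions sharp while remaining quick on a laptop: 1,000 random series for
the step-fit/brute-force equivalence, 100 simulated cohorts for
planted-signature recovery (and 200 at zero effect for the null), 2,000
null genes for type-I calibration, 500 null cohorts of 200 subjects for
log-rank calibration, and 100 planted-hub graphs. Each oracle used in these
checks (exhaustive split search, exhaustive AUC pair counting, step-up BH
enumeration, hand product-limit and observed-minus-expected survival
computations) is an independent transcription of the definition, kept
separate from the implementation it validates.

## Known limitations

* The per-gene test is a Welch t on log values; with very small replicate
  numbers a moderated or count-based model would have better power. The
  package intentionally stops at the simple test.
* Two groups only, everywhere (AUC, Welch, log-rank). Multi-class
  generalizations are out of scope.
* The step threshold is estimated per dataset; scores are therefore not
  directly comparable across datasets, only within.
* Gene identifiers are opaque strings -- no alias or cross-platform symbol
  resolution is attempted.
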