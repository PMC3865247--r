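---
title: "Methods: depth titration for shallow RNA-seq differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth titration for shallow RNA-seq differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowseq)
```

# The question

How little sequencing is enough? For a replicated two-condition RNA-seq
contrast, the number of genes called differentially expressed (DEGs) keeps
rising with read depth long after the genes that matter most — strongly
expressed, strongly differential markers of tissue-specific function — have
been found. `shallowseq` packages the machinery needed to measure this on
any count matrix, and a synthetic-data generator that makes every stage
testable without external data: subsample libraries to a ladder of exact
depths, call DEGs with two independently implemented statistical engines,
and summarise how discovery, effect magnitudes, and marker-set recovery
change with depth.

# The pieces

## Synthetic experiments (`sim_config`, `simulate_experiment`)

The generator emulates the structure of a glandular bulk RNA-seq contrast
with two biological replicates per condition:

* **Heavy-tailed expression.** Relative baseline abundances are log-normal
  with `baseline_sdlog = 2`, giving a transcriptome in which a handful of
  transcripts dominate the read budget — the signature of secretory tissue.
* **A fixed read budget.** Each replicate's counts are one multinomial
  draw of `depth_per_replicate` reads (default 12 million) over genes, so
  column sums are exact. Sequencing depth is a budget, not an expectation,
  which makes subsampling semantics exact downstream.
* **Biological noise.** Per replicate, each gene's rate is multiplied by a
  gamma variate with mean 1 and variance `dispersion` (default
  `phi = 0.05`), so marginal counts are negative-binomial-like. There is
  no published dispersion estimate for the tissues this design emulates;
  0.05 is a typical bulk-tissue value for pooled biological replicates and
  is a modelling choice, not a measured quantity.
* **Planted classes.** 5% of genes are differential with
  `|log2 FC| ~ |N(1.5, 0.8)|` and random sign; 11 "focal" markers are a
  subset of these with baseline above the 90th percentile and
  `|log2 FC| >= 3` (the profile of experimentally verified
  tissue-specific genes); 400 "TF-like" genes have baselines scaled by
  0.1 (transcription factors are expressed well below the gene-wide mean)
  with a third of them differential, matching the observed proportion of
  differentially expressed TFs in the catalog this class mimics.
* Gene lengths are uniform on 500–5000 bp and independent of abundance.

What the generator does **not** emulate: length- or GC-dependent sampling
bias, positional/isoform structure, correlated gene programs, batch
effects, or library-preparation artefacts. Passing tests on this generator
therefore demonstrate the correctness and qualitative behaviour of the
pipeline, not its quantitative performance on any particular real tissue.

## Depth titration (`subsample_counts`, `titrate`)

Each sample is rarefied by a multivariate hypergeometric draw — reads
sampled without replacement from the observed reads — so output column
sums equal the target exactly and no entry grows. Without-replacement
sampling, rather than binomial thinning, mirrors drawing actual reads
from a finite sequenced library. Ladder rungs are independent draws from
the full-depth matrix by default; whether a real titration nests its
draws is rarely documented, and independent draws match "sample N reads
from the larger run" semantics. `nested = TRUE` is available when
monotone rung matrices are wanted. Per-sample random streams are derived
deterministically from `(seed, sample index, rung)`, so runs are
reproducible and order-independent.

## Normalization (`rpkm_normalize`, `uq_normalize`, `size_factors`)

* RPKM: `1e9 * count / (length_bp * total)`, with the total being each
  sample's assigned read count. Mapping-rate totals from an aligner are
  out of scope, so assigned counts are the denominator.
* Upper-quartile: each sample divided by the 75th percentile
  (linear-interpolation quantile) of its *nonzero* counts. Values are
  then put on a fixed scale — the 75th-percentile gene maps to 1000 —
  rather than rescaled by the mean denominator of the experiment at hand.
  The latter keeps values count-like, but a count-like unit grows
  linearly with sequencing depth, which would make the raw-difference
  statistic D incomparable across the rungs of a titration (D among DEGs
  would rise mechanically with depth even as biological differences
  shrink). A fixed unit keeps D depth-comparable; DEG calls are
  unaffected either way because the noise-odds test is invariant to any
  global rescale.
* Size factors: median over all-positive genes of the ratio of each
  sample's count to the gene's geometric mean (median on the ratio
  scale).

Genes that are zero in every sample are carried through normalization
(shapes stay stable across rungs) and removed at testing time.

## The noise-odds engine (`noise_odds_test`)

For each gene the signal is the pair `M = |log2(xA/xB)|`,
`D = |xA - xB|` computed on replicate-averaged normalized values. The
null is the empirical noise distribution: the same (M, D) pairs computed
between replicate samples within the same condition, pooled over both
conditions (a 2 x 2 design contributes `2 * G` noise pairs). The
probability of differential expression is the fraction of noise pairs the
signal strictly dominates in both coordinates, and a gene is called when
this probability exceeds 0.8, the method's conventional cutoff. No
multiple-testing correction is applied — the probability is used
directly, as the method prescribes.

Numerical choices:

* Zeros are replaced by half the smallest positive value of the matrix
  before any ratio is formed — a fixed, scale-aware floor that keeps M
  finite.
* Dominance is strict (`>`), so an exactly-null signal (0, 0) has
  probability exactly 0.
* The dominance count uses a Fenwick tree over D ranks swept in M order,
  `O((G + N) log N)`; the brute-force double loop is kept in the test
  suite as the oracle.

## The NB exact engine (`nb_exact_test`)

The classic small-replicate exact-test formulation:

* Per-gene dispersions by method of moments on size-factor-normalized
  counts, `alpha_raw = max(0, (w - q * zbar) / q^2)` with `w` the pooled
  within-condition variance, `q` the normalized mean, and `zbar` the mean
  reciprocal size factor (shot-noise term). A parametric trend
  `alpha(q) = a1/q + a0` is fitted by least squares against `1/q`, and
  each gene uses `max(raw, fitted)` — the conservative sharing rule that
  was the defensible default when replicates were scarce.
* The test conditions on a gene's grand total: condition totals are NB
  with means `q * sA`, `q * sB` and variances
  `mu + alpha * q^2 * sum(s_j^2)` — the exact variance of a sum of
  independent NB samples. (Collapsing each condition to a single NB
  library with variance `mu + alpha * mu^2` double-counts biological
  variance when there are two replicates; the difference is material for
  marker sensitivity.) The p value is the summed probability of all
  splits no more likely than the observed one, over the probability of
  all splits. Totals above two million reads use a windowed sum covering
  all but a negligible (< 1e-12) share of the conditional mass, always
  including the observed split's neighbourhood.
* Benjamini–Hochberg adjustment across tested genes; called when
  adjusted p < 0.05.

A consequence worth stating plainly: with two replicates the
`max(raw, fitted)` rule inflates dispersion precisely for genes whose
observed scatter is large, so the engine's raw p values are conservative
— on all-null simulations the p < 0.05 fraction sits near 0.03 rather
than 0.05. That is the documented behaviour of this method generation,
not an implementation defect; the package reports it honestly rather than
re-tuning the engine.

## Benchmark surfaces (`run_titration_study` and friends)

Per (depth, engine, normalization): DEG count, mean M and mean D among
called genes, and recovery counts for any supplied gene sets (the
simulated focal and TF sets are tracked automatically). For the NB
engine, M and D are recomputed from size-factor-normalized condition
means (after the same zero replacement) so effect summaries are
comparable across engines; note that size-factor units remain
count-scale, so NB effect magnitudes are comparable across engines
*within* a rung but not across depths — cross-depth effect trends should
be read from the noise-odds rows. `expression_class_test` is a Welch
t-test of a gene set's mean normalized expression against all genes;
`foldchange_correlation` computes Spearman (average ranks on ties) and
Pearson correlations of estimated versus reference log2 fold changes per
depth, the downstream half of a qPCR concordance check.

Fold changes are always condition A over condition B on the log2 scale,
where A is the first condition appearing in the design.

# Reproducibility and problem sizes

All randomness flows from one root seed: the generator seeds the
simulation, and subsampling streams are derived per (seed, sample, rung).
Rerunning `run_titration_study` with the same configuration reproduces
identical tables; the manifest records the seed and a content hash of the
configuration.

The test suite exercises the stochastic properties at sizes chosen to
keep a full run in minutes on one core: oracle equivalences on instances
of up to 500 genes; hypergeometric moment checks over 10 000 seeds on toy
matrices; type-I calibration on ten 10 000-gene all-null simulations at
3 million reads per replicate (a middle rung — deep enough that exact-test
discreteness does not dominate the rejection rate); marker recovery on
five full-depth default simulations; and the depth-trend and
marker-saturation patterns over 20 seeded repetitions of the default
1/3/6/12 M ladder.

# Known limitations

* Exactly two conditions; no covariates, no GLM mode, no shrunken fold
  changes, no outlier refitting.
* The noise-odds engine requires at least one condition with two or more
  replicates; unreplicated designs are not supported.
* The dispersion trend is the parametric `a1/q + a0` least-squares fit —
  simple and reproducible, but less robust to extreme mean-dispersion
  outliers than local regression.
* TMM, quantile and variance-stabilizing normalizations are out of scope.
* The simulator's truth labels make recovery metrics exact, but its
  simplifications (above) mean quantitative sensitivities do not transfer
  to any particular real tissue.
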