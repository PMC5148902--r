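---
title: "Multi-group gene set analysis with few replicates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-group gene set analysis with few replicates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Competitive gene set analysis asks whether a gene set is more associated
with a phenotype contrast than a random set of genes from its complement.
Permutation of *sample* labels (rather than gene labels) is the preferred
way to build the null distribution because it preserves the gene–gene
correlation structure that gene randomization destroys. The catch is
combinatorial: shuffling only the two compared groups ("naive" permutation,
here `perm1`) offers `choose(2n, n) / 2` unique label assignments — with
three replicates per group that is 10, and with five it is 126. A null
distribution assembled from so few distinct values is useless for p-value
estimation in the tail.

This package implements an analysis for *multi-group* designs that borrows
samples from all groups to build the null. The premise is that, apart from
the contrast under study, the same inherent structure — within-group noise
and gene–gene correlation — occurs similarly across all groups, so samples
from the other groups are legitimate material for a null comparison.

# Permutation schemes

Three schemes are implemented behind `generate_permutations()`, with
closed-form space sizes in `count_perm1()`, `count_perm2()` and
`count_perm4_lower()`:

* **perm1** — shuffle only the `2n` samples of the two analyzed groups.
  Valid, but limited to `choose(2n, n)/2` unique splits; `mgszm()` warns
  whenever this is smaller than the requested number of permutations.
* **perm2** — draw `2n` distinct samples uniformly from *all* samples.
  The space grows to `(1/2) y! / (n! n! (y - 2n)!)`, but an unconstrained
  draw can reassemble most of an original group inside one permuted half,
  letting real biological signal leak into the null — or, in strongly
  clustered data, group highly correlated samples and promote false
  negatives.
* **perm4** — the constrained two-stage scheme used by the default
  pipeline. Each half is built by selecting the two analyzed groups plus
  `n − 2` further groups (without replacement), then picking one sample
  uniformly from each selected group; the second half re-selects groups
  independently, with the first half's samples filtered out of every
  group's candidates. Every half therefore contains at most one sample per
  original group and always touches both analyzed groups, so no single
  group can dominate a permuted half. A lower bound for the space is
  `(1/2) n^n (n-1)^n choose(m-2, n-2)^2` for `m > n` — about 2.6e7 for six
  groups of five, versus 126 for perm1.

Draws are independent samples *with replacement* from the permutation
space. The mirror-image factor 1/2 applies to counting only: both
orientations of a split may be drawn, and because the gene-set statistic
folds both directions (below), mirrored draws are equivalent.

**Unequal group sizes.** The counting formulas assume a constant number of
replicates per group, and `perm1`/`perm2` require the two analyzed groups
to have equal size. Real multi-group compendia are rarely balanced, so
`perm4` takes its half size from the *minimum* group size by default
(overridable via `half_size`), requiring more groups than the half size and
at least two samples per group. This makes mixed designs — e.g. two
20-replicate groups analyzed against a backdrop of four 5-replicate groups
— runnable, which is exactly the situation in which one wants to validate
the constrained null against the trustworthy naive one.

# The Gene Set Z-score

Genes are ordered by a differential expression score (descending; ties
broken by gene id for reproducibility) and the running member-score sum

$$X(i) = \sum_{j \le i} s_j \, \mathbf{1}[g_j \in S]$$

is compared with its exact moments under the competitive null, in which the
set's `M` member positions are a uniformly random `M`-subset of all `N`
genes. With `p = M/N`, prefix sums `A1(i), A2(i)` of the scores and their
squares, and `c = M(N-M)/(N^2(N-1))`:

$$E(i) = p\,A1(i), \qquad
  \mathrm{Var}(i) = p(1-p)A2(i) - c\,(A1(i)^2 - A2(i)).$$

These are the running moments of a score-weighted hypergeometric draw; at
`i = N` they reduce to the exact mean and variance of a random `M`-subset's
score sum, and the test suite verifies them against exhaustive subset
enumeration at every position. The standardized profile

$$Z(i) = \frac{X(i) - E(i)}
             {\sqrt{(1-\lambda)\mathrm{Var}(i) + \lambda\overline{\mathrm{Var}} + \varepsilon}}$$

is maximized over positions; the procedure is repeated on the ascending
order (equivalently with negated scores) for down-regulation, and the set
score is the larger of the two directional maxima.

Tuning parameters (all in `gsz_params()`):

* `lambda` (default **0.5**, dimensionless, in `[0,1]`) mixes the
  positional variance with its positional mean
  $\overline{\mathrm{Var}}$. Early positions of the profile have tiny
  hypergeometric variance and would otherwise dominate through noise; the
  mixture damps them while leaving the bulk of the profile essentially
  unchanged. A sensitivity test in the suite confirms the statistic
  responds to `lambda` whenever the variance profile is non-constant.
* `eps` — a small variance floor. By default it resolves to `1e-4` times
  the median (over sets) of $\overline{\mathrm{Var}}$, floored at `1e-12`
  so that an identically zero score vector yields a zero profile rather
  than 0/0. Within a full run the value is resolved once from the
  *observed* score vector and then held fixed for all permutation
  scorings, so observed and null scores are on an identical scale.
* `min_size` / `max_size` (defaults **5** / **2000**) — conventional
  effective-size bounds for curated collections; sets outside are skipped
  and reported.

# Gene-level scores

`score_genes()` provides a Welch t, a log fold change, and the default
**moderated t**: the per-gene pooled variance is shrunk toward the
across-gene mean pooled variance with fixed weight `d0 / (d0 + d)`
(`d0 = 4` pseudo-degrees, `d` the pooled degrees of freedom). This is a
deliberate, fixed-weight approximation of empirical-Bayes variance
moderation: with three replicates per group a full hyperparameter estimate
is itself unstable, while a fixed prior weight gives the stabilization that
matters here (taming near-zero variance estimates). `d0 = 0` recovers the
pooled-variance t exactly. Per-gene variances are additionally floored at
the 5th-percentile *order statistic* (type-1 quantile) of the pooled
variances; the order-statistic choice leaves small gene panels with
distinct variances untouched instead of nudging the smallest one. Scores
are computed on the matrix as given — input is assumed preprocessed
(normalized, log-like scale) and complete; missing values are rejected at
load time rather than imputed, because with three replicates imputation is
more dangerous than refusal.

# Asymptotic p-values

The set score is a maximum over positions and directions, so its
permutation null is modeled with the right-tail Gumbel family,
`F(x) = exp(-exp(-(x-\mu)/\beta))`, fitted per set by maximum likelihood
(profile-likelihood root solve for the scale, closed-form location; a
method-of-moments fallback is recorded in the result if the root solve
fails). The p-value is the fitted upper-tail probability, clamped to
`[1e-300, 1 - 1e-16]`; clamp events are counted and reported, since ties
at the clamp bound are the expected signature of saturated biological
signal. Per-set fitting (never pooled across sets) matters because set
size and internal co-regulation move both Gumbel parameters substantially
between sets. An empirical add-one tail estimate is available as a
cross-check (`pvalue = "empirical"`); the asymptotic route is the default
because a stable Gumbel fit needs only a few hundred permutations where an
empirical tail estimate of comparable resolution needs orders of magnitude
more. The default is `n_perm = 500`; multiple-testing correction is
Benjamini–Hochberg.

# The synthetic data generator

`simulate_dataset()` emulates a balanced multi-group experiment on a
log-like intensity scale: per-gene baselines `N(7, 1.5^2)`, Gaussian
within-group noise of standard deviation `noise_sd`, and gene–gene
correlation injected through one shared latent factor per block — genes in
a block receive `sqrt(rho) f_s + sqrt(1-rho) e_{gs}` noise, giving exact
pairwise correlation `rho` identically in every group (the minimal
construction with a tunable correlation and the same structure across
groups). Each planted ("regulated") set is shifted *up* by
`effect_size × noise_sd` in exactly one designated group — the simplest
unambiguous ground truth for ranking-based evaluation; mixed-direction
sets are intentionally out of scope of the default truth model. Regulated
genes are carved from the front of the gene list and correlation blocks
from the back, kept disjoint so that planted signal and background
correlation can be varied independently.

Defaults (`effect_size = 1`, `noise_sd = 1`, `block_rho = 0.3`, five
blocks of 50 genes) are calibration choices representing a moderate,
realistic regime — a one-noise-SD shift is the kind of effect a
3-replicate design can partially but not trivially detect, and 0.3 is a
typical average within-module expression correlation. They are not values
taken from any particular dataset.

What the generator does **not** emulate: count-based RNA-seq noise
(negative binomial), platform artifacts, outlier samples, unbalanced
designs, or correlated *groups* (e.g. time courses). Tests passing on this
generator therefore show that the machinery is correct and calibrated
under clean Gaussian conditions, not that any particular real dataset
meets those conditions.

`benchmark_sets()` complements the truth model for experiments that need
*unregulated* but realistic set collections: its sets draw a graded
fraction (0 to 1 across the collection) of their members from the
correlation blocks. Curated collections capture co-regulated genes to
widely varying degrees, and that heterogeneity is what spreads per-set
null distributions apart; i.i.d. random sets of similar size have nearly
identical nulls, which makes between-set comparisons of null parameters
(the concordance experiment below) degenerate.

# Evaluation protocols

* **Type-1 error** (`type1_error_experiment()`): group labels are
  randomized (matrix untouched, group sizes preserved), the full pipeline
  is run per replicate, and pooled p-values are compared with Uniform(0,1)
  via the KS statistic and the fraction below 0.05. The harness accepts an
  injected p-value source so its own calibration is testable independently
  of the pipeline. The acceptance-scale experiment uses 6 groups × 3
  replicates, 2000 genes, 200 random sets, 500 permutations and 5
  label-randomization repeats. One caveat a user should know: within one
  comparison all sets share a single observed score vector, so p-values
  are positively dependent — pooled uniformity statistics converge to the
  marginal law only across independent randomizations.
* **Permutation-scheme concordance** (`validate_perm_concordance()`): on a
  design whose analyzed pair has ample replicates (so `perm1` is itself
  trustworthy), per-set Gumbel fits to the `perm1` and `perm4` nulls are
  compared by Pearson correlation across sets and by mean relative error
  (`perm1` as the reference arm, which makes the MRE asymmetric by
  construction). The acceptance-scale experiment uses two 20-replicate
  analyzed groups plus four 5-replicate background groups, 2000 genes, 100
  `benchmark_sets()` collections, 2000 permutations per arm.
* **Data splitting** (`split_dataset()`, `build_reference_sets()`,
  `cumulative_count_curve()`, `split_eval()`): a stratified 25%/75%
  test/reference split; reference gene sets are unions of each
  configuration's top-`n` sets on the reference partition (`n = 3, 5, 7`
  by default), and configurations are scored by the cumulative count of
  reference sets over their top-50 test-partition ranking, averaged over
  `n` and over repeated splits. With a single scoring engine, "methods"
  are configurations (permutation scheme × gene statistic) of that engine.
* **Diluted-set benchmark** (`tissue_benchmark()` with
  `dilute_gene_set()`): planted sets are diluted over a grid of
  replacement percentages (0–90%; round-half-away-from-zero, so a size-10
  set at 90% keeps exactly one original gene), mixed with size-matched
  random sets, and the pipeline is scored by the cumulative relevant-set
  curve and precision–recall AUC (step-wise interpolation / average
  precision, ties broken by set name).
* **Signal recovery across schemes**: at 3 replicates per group and a
  one-SD planted effect (1200 genes, 10 planted + 90 random sets, 200
  permutations, 20 simulation seeds), the `perm4` pipeline's average
  cumulative count of the comparison's planted sets in the top 50 is at
  least the `perm1` pipeline's — the desk-scale analog of the naive
  scheme's degradation on few replicates.

The problem sizes above were chosen as the smallest at which each
property is a stable, meaningful measurement of the phenomenon rather than
noise.

# Numerical choices and degenerate inputs

* Variance clamping: the hypergeometric running variance is clamped at 0
  against floating-point rounding; the positional profile then gets the
  `eps` floor described above.
* Tie-breaks: gene ordering ties break by gene id (ascending); result
  rows sort by ascending p, then descending score, then set name — all
  orderings are total, so identical seeds give byte-identical outputs.
* Gumbel fitting refuses fewer than 50 values or zero spread; the
  asymptotic path in `mgszm()` therefore requires `n_perm >= 50`.
* `perm1` on 3-replicate groups is allowed but warns that its 10 unique
  permutations are fewer than the requested draws.
* Sets whose members are entirely absent from the matrix, or whose
  effective size falls outside the bounds, are skipped with a recorded
  reason rather than silently dropped.

# Known limitations

* Only the three schemes above are implemented; the interface keeps the
  method argument open for further constrained variants.
* Balanced analyzed pairs are required for `perm1`/`perm2`; `perm4`
  handles mixed designs through its half-size rule but still assumes every
  group has at least two samples.
* The moderated t uses fixed-weight shrinkage, not full empirical-Bayes
  moment estimation.
* The Gumbel family fits the body of the max-score null well but is an
  approximation; pooled null p-values are approximately, not perfectly,
  uniform (slightly skewed), matching the behavior expected of this class
  of methods.
* P-values from one comparison are mutually dependent (shared observed
  scores); FDR control via Benjamini–Hochberg is the standard pragmatic
  choice, not an exactness claim.
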