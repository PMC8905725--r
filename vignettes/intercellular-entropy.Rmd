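---
title: "Intercellular entropy: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intercellular entropy: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(icentropy)
```

## The quantity being estimated

For one gene and one set of `N` cells at a comparable differentiation
stage, the raw counts define an empirical distribution over expression
levels; its Shannon entropy (in nats) is the *intercellular entropy* of the
gene at that stage — a measure of cell-to-cell expression variability that
is zero when every cell holds the same count and grows with the spread and
evenness of the count distribution. It is a population measure across cells
at fixed gene, not a per-cell measure across genes.

Three modelling commitments follow from this definition and are kept
throughout the package:

* **Raw counts.** Entropy is computed on raw, non-normalised counts.
  Normalisation maps counts to a continuous scale on which discrete entropy
  is ill-defined, and any per-cell rescaling is itself a source of apparent
  variability. An optional per-window depth-downsampling switch exists on
  `window_profiles()` as a clearly labelled extension, but it is off by
  default and not part of the standard analysis.
* **Nats.** All entropies use the natural logarithm; that is the unit the
  estimator theory below is written in. Dividing by `log(2)` converts to
  bits for display.
* **Binning.** The bins are the integer expression levels `0 .. max`, so
  the bin count is `m = max(counts) + 1` (`m_policy = "max_plus_one"`).
  The zero level is always a bin, and unobserved intermediate levels count
  toward `h_0`. The alternative reading (only observed values form bins) is
  available as `m_policy = "observed_support"`; the choice affects only
  `h_0` and hence only estimators that weight empty bins (BUB). When the
  true support is known — in simulations — `m` can be passed explicitly.
  An all-zero gene (`m = 1`) has entropy 0 by definition under every
  estimator: a degenerate support admits no variability.

## Estimators

All four estimators are linear in the occupancy vector `h_j` = number of
bins occupied by exactly `j` cells (`summarize_histogram()`), the
sufficient statistic for this problem.

* **Plugin** (maximum likelihood): `−Σ_{j≥1} h_j (j/N) log(j/N)`. Biased
  low, severely so when `N/m` is small.
* **Miller–Madow**: plugin `+ (observed bins − 1)/(2N)`; the first-order
  bias correction.
* **Jackknife**: `N·Ĥ − (N−1)/N · Σ_i Ĥ_{(−i)}`. Implemented by grouping
  the leave-one-out terms over distinct levels (cells sharing a level have
  identical leave-one-out estimates), which turns an `O(N·levels)` loop
  into `O(levels²)`.
* **BUB** (best upper bound; Paninski 2003): coefficients `a_j` chosen to
  minimise an explicit bound on the worst-case RMS error over all
  distributions on `m` bins.

### The BUB construction

The expectation of a linear estimator is `Σ_bins Σ_j a_j B_{j,N}(p_bin)`
with `B_{j,N}` the Bernstein basis, so the worst-case bias is at most
`m · max_p |Σ_j a_j B_{j,N}(p) + p log p|`, and by bounded differences
(changing one cell moves `Ĥ` by at most `2 max_j |a_{j+1} − a_j|`) the
variance is at most `N (max_j |a_{j+1} − a_j|)²`. `bub_coefficients()`
minimises a least-squares surrogate of this bound:

* free coefficients `j ≤ k_max` are fitted to the entropy integrand
  `−p log p` on a uniform mesh over `[0, 1]` (2000 points by default), with
  the residuals **weighted by `m`** so that the squared fit term lives on
  the scale of the squared bias bound. This weighting is essential: with an
  unweighted fit the smoothness penalty overwhelms the data term by orders
  of magnitude and the resulting estimator is far worse than plugin. It
  also means the coefficients genuinely depend on `(N, m)`, not on `N`
  alone;
* a ridge penalty `λ Σ_j (a_{j+1} − a_j)²` controls the variance bound;
  `λ` is searched over `{0, N/4, N, 4N}` and `k_max` over
  `{10, 20, 30, min(N, 60)}`, and the candidate with the smallest combined
  bound `sqrt((m·max|res|)² + N·max|Δa|²)` is returned, together with that
  bound (`error_bound`);
* coefficients `j > k_max` are anchored to the bias-corrected plugin form
  `−(j/N) log(j/N) + 1/(2N)`: levels seen many times are well estimated by
  the plugin rule, and anchoring keeps the free problem small (≤ 61
  unknowns) at any `N`.

Numerical choices: the Bernstein basis is evaluated in log space
(`lchoose` + logs) so it is stable at `N = 700` and beyond, and built in
mesh chunks so the full `mesh × (N+1)` matrix is never materialised; the
`−p log p` target at `p = 0` is defined as 0 (continuous extension); a
`1e-10`-scaled Tikhonov jitter keeps the `λ = 0` normal equations solvable
(the full-degree Bernstein Gram matrix is numerically singular) — such
candidates then lose the bound comparison on their own merits rather than
crashing the grid search.

Because `m` differs per gene and window while `N` is fixed per run,
coefficient solving is memoised at two levels (`bub_cache()`): the mesh
design and normal-equation blocks once per `N`, the penalised solves and
bound minimisation once per `(N, m)`. The cache can be dumped to TSV
(`write_bub_cache()`) for audits.

The test suite pins the estimator contracts: exact agreement of
plugin/Miller–Madow/jackknife with brute-force formulas; the fit equal to
an independent stacked-QR solution of the same objective; empirical RMSE
below `error_bound` on point-mass, uniform and Zipf distributions; and, at
`N = 50, m = 100` over the stress family, a smaller worst-case RMSE for
BUB than for any comparator.

## Trajectory profiles

Cells of one pathway (membership by population label, `pathway_spec()`)
are ordered by a supplied pseudotime — pseudotime inference itself is out
of scope and consumed as an input — with ties broken lexicographically by
cell id so orderings are reproducible. Windows are full only: a window of
50 cells advancing by 10 yields `floor((n − 50)/10) + 1` windows and no
ragged tail, so every window's entropy is estimated at the same `N`.
Each window is labelled by its first cell's population.

The per-window mean entropy averages over the **full gene set**, including
genes all-zero in the window (contributing 0). Averaging over a fixed gene
set keeps profiles comparable across windows: the number of detected genes
varies along a trajectory, and a detected-only average would confound
variability with detection. This is the one place where the alternative
(average over locally detected genes) was a genuinely open choice; the
fixed-set reading makes the mean a proper average of a fixed random vector
and is the one implemented.

`peak_summary()` reports the argmax window (earliest on ties) and flags the
peak as transient when it strictly exceeds both the first and last window —
a minimal operationalisation of "a transient peak" that is robust to
monotone drifts at either end.

## Delta analysis

Per gene and pathway, `delta_entropy` and `delta_expression` are max − min
of the window entropy and window mean expression. Rankings break ties
lexicographically by gene id, so top-k lists are deterministic. The
delta–delta correlation defaults to Pearson on `log1p`-transformed deltas:
both deltas are heavy-tailed and inspected on log scales, and the raw-scale
Pearson would be driven by a handful of extreme genes. The method and
transform are recorded in the output and both are switchable
(`method = "spearman"`, `log_transform = FALSE`).

## Group comparison

`hsc_entropy_comparison()` contrasts two cell populations: in each of 100
iterations it draws 700 cells per sample without replacement, computes
per-gene BUB entropy over the whole subsample (a single window of
`N = 700`), records each sample's mean entropy over genes, and compares the
two per-gene entropy vectors with a two-sided Wilcoxon test, tallying
p-values against the tiers 0.05/0.01/0.001/0.0001. Iteration `i` seeds its
own derived stream, so results are reproducible and iterations independent.
Dissociation-induced stress genes (the intersection of two published
signatures, `dissociation_gene_set()`) can be excluded from both samples
when the samples' dissociation protocols differ.

Two test variants exist because "a Wilcoxon test on per-gene entropies"
admits two readings, and they behave very differently under the null:

* `rank_sum` (default): two-sided Wilcoxon rank-sum between the two
  per-gene entropy vectors. Genes differ hugely in baseline entropy, and
  that between-gene spread — not the group label — dominates the pooled
  ranking; the statistic's true null variance is therefore far smaller
  than the iid null variance the test assumes, making the variant
  **conservative** (null p-values pile up near 1). It is kept as the
  default because it is the natural reading and conservative inference is
  the safe failure mode.
* `signed_rank_paired_by_gene`: Wilcoxon signed-rank on per-gene entropy
  differences. Under the null each difference is symmetric about zero
  independently across genes, so this variant is **exactly calibrated**
  even with heteroscedastic genes.

The calibration test asserts the ~5% type-I rate for the paired variant
and a silent strictest tier for the default variant, which is exactly what
the statistics above predict. The variant used is stamped into every
output.

## The synthetic generator

`simulate_trajectory()` emulates the features of real droplet scRNA-seq
data that the analysis relies on: integer counts with negative-binomial
overdispersion; gene means varying smoothly along a latent pseudotime on a
uniform grid; per-cell lognormal library-size factors (σ = 0.2, mean 1);
contiguous pseudotime segments as population labels; and a transient
variability window implemented as a Gaussian-shaped *dispersion bump* that
divides every gene's NB size parameter by `1 + A exp(−(t−c)²/(2w²))`.
Three gene classes give the delta analysis something to dissociate:

* *switch* genes: sigmoid means between 0.2 and 8 counts with per-gene
  switch times in a band around the bump centre and moderate dispersion
  (size 4). Genes switching before the centre switch on, genes after it
  switch off — a transient activation program. This has two deliberate
  consequences: every switch gene is in its high state during the
  variability window (so its true window entropy is maximised inside the
  band, a property the oracle tests check), and the on/off split makes the
  sustained high-state entropy plateaus cancel between the trajectory ends
  (so the global profile peak is carried by the bump, not by a monotone
  drift);
* *housekeeping* genes: high-amplitude linear mean ramps (base
  ~ Lognormal(log 20, 0.3), tripling along the trajectory) with low
  dispersion (size 50) — large expression change, stable variability;
* *noise* genes: constant lognormal means (median e ≈ 2.7), size 8.

Baseline sizes deliberately sit in the regime where extra dispersion
**raises** discrete NB entropy. This regime matters and is easy to get
wrong: at fixed mean, NB entropy is non-monotone in dispersion — below
size ≈ 1–2 the distribution becomes zero-inflated and entropy *falls* as
dispersion grows. A bump acting on strongly overdispersed baselines would
produce an entropy dip; acting on size 8 → 2 it produces the intended peak.
The same consideration fixes the two-group design
(`simulate_two_group_hsc()`): shared means ~ Lognormal(2, 0.5) — a
well-expressed gene panel — control size 4, and case size divided by
ρ = 1.5, giving a per-gene true entropy increase of ≈ 0.04–0.13 nats across
the mean range, consistently positive, which the subsampled comparison
detects in every iteration at the strictest tier.

Defaults are 2000 cells × 2000 genes (300 switch / 200 housekeeping /
1500 noise), bump `A = 3`, `c = 0.5`, `w = 0.03`. The bump width is chosen
so that the profile's curvature at the peak exceeds the window-to-window
Monte-Carlo noise of the gene-averaged entropy at this grid, making the
argmax localisable to a couple of windows.

What the generator does **not** emulate: batch and donor effects, doublets,
ambient RNA, branching topologies, gene–gene correlation, and
mean–dispersion trends fitted from real data. Passing tests therefore
demonstrate that the pipeline recovers planted variability structure from
NB-distributed counts at realistic depths — not that any particular
biological dataset contains such structure.

`true_window_entropy()` is the ground-truth oracle: a Monte-Carlo estimate
(bias-corrected plugin on ≥ 1e5 mixture draws, block standard errors) of
the entropy of the count mixture induced by a window's NB parameters. The
suite checks it against the closed-form geometric case
(`NB(μ=1, size=1)`, `H = 2 log 2`) and uses it to verify that estimated
window entropies track the truth (`r ≥ 0.9` over random gene–window
pairs).

## Problem sizes used by the test suite

Full-size runs are used where the claim depends on the size (the two-group
comparison twin: 2000 × 2000, 100 subsamples of 700; the bump-recovery
profile: 2000 × 2000, 196 windows). Properties that are size-free —
null calibration, flat-profile noise envelopes, oracle tracking,
dissociation of the delta rankings — run on scaled configurations
(600–1000 cells, 400–600 genes, 20 subsamples of 300) chosen so the whole
suite completes in a couple of minutes while keeping every statistical
margin wide.

## Known limitations

* Entropy estimates at different windows share no information; no
  smoothing or borrowing across windows is attempted, by design.
* The BUB bound is a worst-case bound over all distributions on `m` bins;
  for the particular distributions of real genes it can be loose by
  several-fold.
* `m = max(count) + 1` makes `m` itself random; the coefficients treat it
  as fixed, a standard approximation in this setting.
* The rank-sum default is conservative under gene-level heterogeneity (see
  above); users wanting calibrated p-values should use the paired variant.
* Multi-sample (> 2) comparisons, batch correction and sample integration
  are out of scope.
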