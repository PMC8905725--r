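# icentropy

Cell-to-cell gene expression variability — *intercellular entropy* — along
single-cell differentiation trajectories.

During differentiation, cells do not move deterministically from one
transcriptional state to the next: around fate commitment, gene expression
becomes transiently more heterogeneous across cells before settling into the
mature program. `icentropy` quantifies this from raw scRNA-seq counts. For
one gene and one window of `N` cells ordered along a pseudotime, the counts
define an empirical distribution over expression levels; its Shannon entropy

&nbsp;&nbsp;&nbsp;&nbsp;`H = − Σ_x p(x) log p(x)`&nbsp;&nbsp;(nats)

measures how differently the cells in that window express the gene. Sliding
a window of 50 cells with a step of 10 along the trajectory, and averaging
the per-gene entropies over all genes, yields a variability profile of the
differentiation pathway; a transient peak in that profile marks the window
of maximal cell-to-cell heterogeneity.

Entropy estimation in this setting is severely undersampled: a window holds
`N = 50` cells while a gene may occupy `m ≈ 100` distinct count levels. The
package therefore centres on the **Best Upper Bound (BUB) estimator**
(Paninski 2003, *Neural Computation* 15:1191–1253), a linear estimator

&nbsp;&nbsp;&nbsp;&nbsp;`Ĥ = Σ_j a_j h_j`

on the occupancy vector `h_j` (the number of expression levels held by
exactly `j` cells), whose coefficients minimise an explicit upper bound
combining a Bernstein-approximation bias term (`m · max_p |residual|`) and a
bounded-differences variance term (`N · max_j |a_{j+1} − a_j|²`). The
plugin (maximum-likelihood), Miller–Madow and jackknife estimators are
provided as comparators; in the `N/m < 100` regime the test suite verifies
that BUB has the smallest worst-case RMSE of the four.

On top of the estimator the package implements the full downstream
analysis:

* **matrix I/O and QC** — 10x-style Matrix Market triplets and dense
  TSV/CSV, with cell filtering by detected-gene band and mitochondrial
  fraction (`qc_filter_cells()`);
* **trajectory profiles** — pathway selection, pseudotime ordering,
  sliding-window per-gene entropy / mean expression, peak location
  (`build_ordering()`, `window_profiles()`, `peak_summary()`);
* **delta analysis** — per-gene delta-entropy and delta-expression
  (max − min across windows), top-k lists, cross-pathway overlaps, the
  delta–delta correlation, and transcription-factor subsets
  (`compute_deltas()`, `top_k()`, `overlap_lists()`, `tf_subset()`);
* **group comparison** — the subsampled contrast of two cell populations
  (e.g. dysplastic vs healthy HSC compartments): repeated equal-size
  subsamples, per-gene BUB entropy, two-sided Wilcoxon tests and
  significance-tier tallies (`hsc_entropy_comparison()`), plus per-cell-type
  equalisation (`equalize_celltypes()`) and dissociation-gene exclusion;
* **synthetic data** — negative-binomial generators with smooth mean
  trajectories, a programmable transient dispersion bump, switch vs
  housekeeping gene classes and a two-group HSC design, with ground-truth
  entropy oracles (`simulate_trajectory()`, `simulate_two_group_hsc()`,
  `true_window_entropy()`).

## Worked example

Simulate a 600-cell trajectory with a variability bump at pseudotime 0.5,
profile it, and rank genes by their entropy and expression dynamics:

```r
library(icentropy)

ds  <- simulate_trajectory(trajectory_config(
         n_cells = 600, n_switch_genes = 60,
         n_housekeeping_genes = 40, n_noise_genes = 300, seed = 1))
ord <- build_ordering(ds$matrix, ds$annotation, ds$pseudotime,
                      pathway_spec("simulated", paste0("stage", 1:5)))
#> pathway 'simulated': 600 cells ordered

prof <- window_profiles(ord, ds$matrix)
prof
#> window_profiles 'simulated': 400 genes x 56 windows (size 50, step 10, bub estimator)
#>   mean entropy range [2.1044, 2.4262] nats

peak_summary(prof)
#> $argmax       [1] 29
#> $label        [1] "stage3"
#> $is_transient [1] TRUE
```

Window 29 of 56 sits at pseudotime ≈ 0.51 — the profile peaks at the
planted bump (centre 0.5), in the middle population, and the peak is
transient (higher than both trajectory ends). The delta rankings dissociate
the two gene classes: genes that *switch states* dominate delta-entropy,
highly expressed *housekeeping* ramps dominate delta-expression:

```r
dt <- compute_deltas(prof)
top_k(dt, "delta_entropy", k = 5)
#> top 5 genes by delta_entropy in 'simulated':
#> SW0019 SW0025 SW0016 SW0060 SW0040
#> 3.1303 3.0409 3.0029 2.9615 2.9575

top_k(dt, "delta_expression", k = 5)
#> top 5 genes by delta_expression in 'simulated':
#> HK0031 HK0040 HK0026 HK0038 HK0001
#>  73.50  71.34  70.32  59.24  56.84

delta_correlation(dt)[c("r", "p", "n")]
#> r = 0.683, p = 3.08e-56, n = 400
```

The two deltas correlate, but far from perfectly — variability dynamics and
expression dynamics single out different genes.

A YAML-driven command-line interface over the same functions is installed
at `inst/cli/icentropy.R` (subcommands `simulate`, `entropy-profile`,
`delta`, `compare`); see `?read_run_config` for the configuration schema.

## References

Paninski L (2003). Estimation of entropy and mutual information.
*Neural Computation* 15:1191–1253.
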