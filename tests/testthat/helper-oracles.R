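# Independent brute-force oracles used to freeze expected values.

# Plugin entropy straight from the definition, bypassing occupancy vectors.
oracle_plugin <- function(counts) {
  p <- as.numeric(table(counts)) / length(counts)
  -sum(p * log(p))
}

# Occupancy vector by literal double tally: cells per level, then levels
# per occupancy.
oracle_occupancy <- function(counts, m) {
  levels <- 0:(m - 1)
  per_level <- vapply(levels, function(l) sum(counts == l), integer(1))
  vapply(0:length(counts), function(j) sum(per_level == j), numeric(1))
}

# Jackknife by a literal leave-one-out loop.
oracle_jackknife <- function(counts) {
  N <- length(counts)
  loo <- vapply(seq_len(N), function(i) oracle_plugin(counts[-i]), numeric(1))
  N * oracle_plugin(counts) - ((N - 1) / N) * sum(loo)
}

# One shared coefficient cache across the whole suite: coefficients are
# deterministic, so reuse is free and keeps the suite fast.
shared_cache <- bub_cache()

# Small trajectory configuration reused by several tests.
small_traj_config <- function(n_cells = 600L, n_switch_genes = 60L,
                              n_housekeeping_genes = 40L,
                              n_noise_genes = 300L, ...) {
  trajectory_config(n_cells = n_cells, n_switch_genes = n_switch_genes,
                    n_housekeeping_genes = n_housekeeping_genes,
                    n_noise_genes = n_noise_genes, ...)
}

# Stress family of distributions over m bins for undersampled-regime tests.
stress_family <- function(m) {
  zipf <- (1 / seq_len(m)) / sum(1 / seq_len(m))
  list(uniform = rep(1 / m, m),
       zipf = zipf,
       half_uniform = c(rep(2 / m, m %/% 2), rep(0, m - m %/% 2)),
       point_mass = c(1, rep(0, m - 1)))
}

true_entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
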