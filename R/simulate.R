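#' Configuration for a synthetic differentiation trajectory
#'
#' Emulates the count structure the trajectory analysis assumes: integer
#' counts with gene-specific means varying smoothly along a latent
#' pseudotime on a uniform grid over `[0, 1]`, negative-binomial
#' overdispersion, a programmable transient window of elevated cell-to-cell
#' variability (a Gaussian-shaped "dispersion bump" dividing every gene's NB
#' size parameter by `1 + A exp(-(t - c)^2 / (2 w^2))`), and per-cell
#' library-size variation. Three gene classes are generated:
#'
#' * switch genes: sigmoid mean
#'   \eqn{\mu_{lo} + (\mu_{hi}-\mu_{lo}) / (1 + e^{-s (t - t_{0g})})} with
#'   per-gene switch times scattered in a transition band around the bump
#'   centre, moderate dispersion. Genes switching before the bump centre
#'   switch on and genes switching after it switch off (a transient
#'   activation program), so every switch gene is in its high state during
#'   the variability window, and the on/off split makes their sustained
#'   entropy plateaus cancel between the two ends of the trajectory;
#' * housekeeping genes: smooth high-amplitude linear mean ramp (base to
#'   `ramp_factor` x base) with low dispersion — large expression change,
#'   stable variability;
#' * noise genes: constant lognormal means, high dispersion.
#'
#' Defaults (2000 cells x 2000 genes, 300/200/1500 split, bump `A = 3`,
#' `c = 0.5`, `w = 0.03`) give a desk-scale dataset whose mean-entropy
#' profile carries one clear transient peak. Baseline NB sizes sit in the
#' regime where extra dispersion raises discrete entropy (size well above
#' ~1; below that, zero-inflation makes NB entropy fall as dispersion
#' grows, which would invert the bump).
#'
#' @param n_cells number of cells (uniform pseudotime grid).
#' @param n_switch_genes,n_housekeeping_genes,n_noise_genes class sizes.
#' @param mu_lo,mu_hi,slope,t0_band sigmoid parameters of switch genes
#'   (`t0_band`: 2-vector bounding the per-gene switch times).
#' @param hk_base_meanlog,hk_base_sdlog,hk_ramp_factor housekeeping base
#'   levels (lognormal) and ramp amplitude.
#' @param noise_meanlog,noise_sdlog lognormal parameters of noise-gene
#'   means.
#' @param size_switch,size_housekeeping,size_noise baseline NB size
#'   (inverse-dispersion) per class; smaller = noisier.
#' @param bump_amplitude,bump_center,bump_width dispersion bump `A >= 0`,
#'   `c`, `w`.
#' @param sigma_lib standard deviation (log scale) of the lognormal per-cell
#'   library-size multiplier (mean 1).
#' @param n_stages number of contiguous pseudotime segments used as
#'   population labels (`"stage1" ...`).
#' @param seed RNG seed; generation is bitwise-deterministic given the
#'   config.
#' @return an object of class `"trajectory_config"`.
#' @export
trajectory_config <- function(n_cells = 2000L, n_switch_genes = 300L,
                              n_housekeeping_genes = 200L,
                              n_noise_genes = 1500L,
                              mu_lo = 0.2, mu_hi = 8, slope = 30,
                              t0_band = c(0.35, 0.65),
                              hk_base_meanlog = log(20), hk_base_sdlog = 0.3,
                              hk_ramp_factor = 3,
                              noise_meanlog = 1, noise_sdlog = 1,
                              size_switch = 4, size_housekeeping = 50,
                              size_noise = 8,
                              bump_amplitude = 3, bump_center = 0.5,
                              bump_width = 0.03,
                              sigma_lib = 0.2, n_stages = 5L, seed = 1L) {
  if (bump_amplitude < 0) stop_config("bump_amplitude must be >= 0")
  if (mu_lo <= 0 || mu_hi <= 0) stop_config("means must be > 0")
  if (length(t0_band) != 2L || t0_band[1L] > t0_band[2L])
    stop_config("t0_band must be an increasing 2-vector")
  structure(as.list(environment()), class = "trajectory_config")
}

# Per-gene NB parameters at pseudotimes t (vector), before the library-size
# multiplier. Returns list(mu, size), each length(t).
gene_nb_params <- function(truth, gene_id, t) {
  cfg <- truth$config
  i <- match(gene_id, truth$gene_ids)
  if (is.na(i)) stop_config("unknown gene '", gene_id, "'")
  cls <- truth$gene_class[i]
  mu <- switch(cls,
    switch = sigmoid_mean(t, truth$t0[i], truth$direction[i], cfg),
    housekeeping = truth$hk_base[i] *
      (1 + (cfg$hk_ramp_factor - 1) * t),
    noise = rep(truth$noise_mu[i], length(t)))
  base_size <- switch(cls, switch = cfg$size_switch,
                      housekeeping = cfg$size_housekeeping,
                      noise = cfg$size_noise)
  bump <- 1 + cfg$bump_amplitude *
    exp(-(t - cfg$bump_center)^2 / (2 * cfg$bump_width^2))
  list(mu = mu, size = base_size / bump)
}

# Sigmoid switch mean; direction +1 switches on (mu_lo -> mu_hi), -1 off.
sigmoid_mean <- function(t, t0, direction, cfg) {
  s <- cfg$mu_lo + (cfg$mu_hi - cfg$mu_lo) / (1 + exp(-cfg$slope * (t - t0)))
  if (direction >= 0) s else (cfg$mu_lo + cfg$mu_hi - s)
}

#' Simulate a differentiation trajectory with ground truth
#'
#' @param config a [trajectory_config()].
#' @return list with `matrix` (a `"count_matrix"`), `annotation`
#'   (cell_id / population_label / sample_id), `pseudotime`
#'   (cell_id / pseudotime) and `ground_truth` (gene classes, per-gene
#'   switch times, bump parameters, library factors and the config; feeds
#'   [true_window_entropy()] via [gene_nb_params()]).
#' @export
simulate_trajectory <- function(config = trajectory_config()) {
  if (!inherits(config, "trajectory_config"))
    stop_config("config must be a trajectory_config")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    t <- seq(0, 1, length.out = n)
    gene_ids <- c(sprintf("SW%04d", seq_len(cfg$n_switch_genes)),
                  sprintf("HK%04d", seq_len(cfg$n_housekeeping_genes)),
                  sprintf("NS%04d", seq_len(cfg$n_noise_genes)))
    gene_class <- rep(c("switch", "housekeeping", "noise"),
                      c(cfg$n_switch_genes, cfg$n_housekeeping_genes,
                        cfg$n_noise_genes))
    t0 <- rep(NA_real_, length(gene_ids))
    t0[gene_class == "switch"] <-
      stats::runif(cfg$n_switch_genes, cfg$t0_band[1L], cfg$t0_band[2L])
    direction <- rep(NA_real_, length(gene_ids))
    direction[gene_class == "switch"] <-
      ifelse(t0[gene_class == "switch"] <= cfg$bump_center, 1, -1)
    hk_base <- rep(NA_real_, length(gene_ids))
    hk_base[gene_class == "housekeeping"] <-
      stats::rlnorm(cfg$n_housekeeping_genes, cfg$hk_base_meanlog,
                    cfg$hk_base_sdlog)
    noise_mu <- rep(NA_real_, length(gene_ids))
    noise_mu[gene_class == "noise"] <-
      stats::rlnorm(cfg$n_noise_genes, cfg$noise_meanlog, cfg$noise_sdlog)
    # library multipliers, mean 1
    lib <- stats::rlnorm(n, -cfg$sigma_lib^2 / 2, cfg$sigma_lib)
    truth <- list(config = cfg, gene_ids = gene_ids, gene_class = gene_class,
                  t0 = t0, direction = direction, hk_base = hk_base,
                  noise_mu = noise_mu, t = t, lib = lib)
    counts <- matrix(0L, length(gene_ids), n)
    for (i in seq_along(gene_ids)) {
      pars <- gene_nb_params(truth, gene_ids[i], t)
      counts[i, ] <- stats::rnbinom(n, mu = pars$mu * lib, size = pars$size)
    }
    cell_ids <- sprintf("cell%05d", seq_len(n))
    stage <- paste0("stage", ceiling(seq_len(n) / n * cfg$n_stages))
    mat <- count_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids)
    list(matrix = mat,
         annotation = data.frame(cell_id = cell_ids,
                                 population_label = stage,
                                 sample_id = "sim",
                                 stringsAsFactors = FALSE),
         pseudotime = data.frame(cell_id = cell_ids, pseudotime = t,
                                 stringsAsFactors = FALSE),
         ground_truth = truth)
  })
}

#' Simulate several pathways sharing housekeeping and noise genes
#'
#' Generates `n_pathways` trajectories over one gene universe: each pathway
#' has its own private switch genes (flat at `mu_lo` in every other
#' pathway), while housekeeping and noise genes keep identical per-gene
#' parameters in all pathways. This reproduces the qualitative structure in
#' which top delta-entropy lists are pathway-specific and top
#' delta-expression lists are shared.
#'
#' @param n_pathways number of pathways (>= 2).
#' @param config a [trajectory_config()]; per-pathway seeds are derived from
#'   `config$seed`.
#' @return list with one element per pathway (`pathway1`, ... each as
#'   [simulate_trajectory()] output with pathway-specific cell ids) and an
#'   attribute `"gene_owner"` naming, for each switch gene, its pathway.
#' @export
simulate_pathway_set <- function(n_pathways = 3L,
                                 config = trajectory_config()) {
  if (n_pathways < 2L) stop_config("need >= 2 pathways")
  cfg <- config
  # Shared gene universe: per-pathway switch blocks + common HK/noise.
  shared <- with_seed(cfg$seed, list(
    hk_base = stats::rlnorm(cfg$n_housekeeping_genes, cfg$hk_base_meanlog,
                            cfg$hk_base_sdlog),
    noise_mu = stats::rlnorm(cfg$n_noise_genes, cfg$noise_meanlog,
                             cfg$noise_sdlog)))
  gene_ids <- c(unlist(lapply(seq_len(n_pathways), function(p)
    sprintf("SW_P%d_%04d", p, seq_len(cfg$n_switch_genes)))),
    sprintf("HK%04d", seq_len(cfg$n_housekeeping_genes)),
    sprintf("NS%04d", seq_len(cfg$n_noise_genes)))
  owner <- c(rep(paste0("pathway", seq_len(n_pathways)),
                 each = cfg$n_switch_genes),
             rep(NA_character_,
                 cfg$n_housekeeping_genes + cfg$n_noise_genes))
  out <- vector("list", n_pathways)
  names(out) <- paste0("pathway", seq_len(n_pathways))
  for (p in seq_len(n_pathways)) {
    out[[p]] <- with_seed(derive_seed(cfg$seed, p), {
      n <- cfg$n_cells
      t <- seq(0, 1, length.out = n)
      cls <- ifelse(is.na(owner), ifelse(startsWith(gene_ids, "HK"),
                                         "housekeeping", "noise"),
                    ifelse(owner == names(out)[p], "switch", "flat_switch"))
      t0 <- rep(NA_real_, length(gene_ids))
      t0[cls == "switch"] <- stats::runif(cfg$n_switch_genes,
                                          cfg$t0_band[1L], cfg$t0_band[2L])
      direction <- rep(NA_real_, length(gene_ids))
      direction[cls == "switch"] <-
        ifelse(t0[cls == "switch"] <= cfg$bump_center, 1, -1)
      hk_base <- noise_mu <- rep(NA_real_, length(gene_ids))
      hk_base[cls == "housekeeping"] <- shared$hk_base
      noise_mu[cls == "noise"] <- shared$noise_mu
      lib <- stats::rlnorm(n, -cfg$sigma_lib^2 / 2, cfg$sigma_lib)
      bump <- 1 + cfg$bump_amplitude *
        exp(-(t - cfg$bump_center)^2 / (2 * cfg$bump_width^2))
      counts <- matrix(0L, length(gene_ids), n)
      for (i in seq_along(gene_ids)) {
        mu <- switch(cls[i],
          switch = sigmoid_mean(t, t0[i], direction[i], cfg),
          flat_switch = rep(cfg$mu_lo, n),
          housekeeping = hk_base[i] * (1 + (cfg$hk_ramp_factor - 1) * t),
          noise = rep(noise_mu[i], n))
        size <- switch(cls[i], switch = , flat_switch = cfg$size_switch,
                       housekeeping = cfg$size_housekeeping,
                       noise = cfg$size_noise) / bump
        counts[i, ] <- stats::rnbinom(n, mu = mu * lib, size = size)
      }
      cell_ids <- sprintf("p%d_cell%05d", p, seq_len(n))
      stage <- paste0("stage", ceiling(seq_len(n) / n * cfg$n_stages))
      list(matrix = count_matrix(counts, gene_ids, cell_ids),
           annotation = data.frame(cell_id = cell_ids,
                                   population_label = stage,
                                   sample_id = names(out)[p],
                                   stringsAsFactors = FALSE),
           pseudotime = data.frame(cell_id = cell_ids, pseudotime = t,
                                   stringsAsFactors = FALSE),
           gene_class = cls)
    })
  }
  attr(out, "gene_owner") <- stats::setNames(owner, gene_ids)
  out
}

#' Configuration for the two-group HSC comparison design
#'
#' Two populations share one lognormal per-gene mean vector; the case group
#' has its NB size parameter divided by `rho` (i.e. `rho`-fold dispersion
#' inflation), the synthetic analogue of a variability-inflated stem-cell
#' compartment contrasted with a healthy control. The defaults model a
#' well-expressed gene panel (means ~ Lognormal(2, 0.5), median ~7 counts)
#' with moderate overdispersion (`size0 = 4`), a regime where dispersion
#' inflation raises the discrete count entropy for essentially every gene
#' (at very small NB sizes, zero-inflation would make entropy fall
#' instead).
#'
#' @param n_cells cells per group (default 2000).
#' @param n_genes genes (default 2000).
#' @param meanlog,sdlog lognormal parameters of the shared mean vector.
#' @param size0 control NB size parameter.
#' @param rho case dispersion multiplier (>= 1; case size = `size0 / rho`).
#' @param seed RNG seed.
#' @return an object of class `"two_group_config"`.
#' @export
two_group_config <- function(n_cells = 2000L, n_genes = 2000L,
                             meanlog = 2, sdlog = 0.5,
                             size0 = 4, rho = 1.5, seed = 42L) {
  if (rho < 1) stop_config("rho must be >= 1")
  if (size0 <= 0) stop_config("size0 must be > 0")
  structure(as.list(environment()), class = "two_group_config")
}

#' Simulate control and dispersion-inflated HSC-like count matrices
#'
#' @param config a [two_group_config()].
#' @return list with `control` and `case` (`"count_matrix"` objects, genes
#'   shared, all cells labelled implicitly as one population) and `truth`
#'   (`mu`, `size0`, `rho`).
#' @export
simulate_two_group_hsc <- function(config = two_group_config()) {
  if (!inherits(config, "two_group_config"))
    stop_config("config must be a two_group_config")
  cfg <- config
  with_seed(cfg$seed, {
    mu <- stats::rlnorm(cfg$n_genes, cfg$meanlog, cfg$sdlog)
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    draw <- function(size, prefix) {
      m <- matrix(stats::rnbinom(cfg$n_genes * cfg$n_cells,
                                 mu = mu, size = size),
                  cfg$n_genes, cfg$n_cells)
      count_matrix(m, gene_ids,
                   sprintf("%s%05d", prefix, seq_len(cfg$n_cells)))
    }
    control <- draw(cfg$size0, "ctrl")
    case <- draw(cfg$size0 / cfg$rho, "case")
    list(control = control, case = case,
         truth = list(mu = mu, size0 = cfg$size0, rho = cfg$rho))
  })
}

#' Monte-Carlo oracle for the true entropy of a window's count mixture
#'
#' A window of cells with (possibly different) NB parameters induces one
#' mixture distribution over counts; its Shannon entropy is the ground truth
#' the window estimators target. Estimated by Monte-Carlo: draw a cell
#' uniformly, then a count from its NB law, and take the bias-corrected
#' plugin entropy of the draws. The standard error comes from 10 independent
#' blocks.
#'
#' @param mu,size NB mean and size vectors over the window's cells
#'   (recycled to a common length).
#' @param n_draws Monte-Carlo sample size (default 1e5).
#' @param seed RNG seed.
#' @return list with `value` (nats) and `se`.
#' @export
true_window_entropy <- function(mu, size, n_draws = 1e5L, seed = 1L) {
  k <- max(length(mu), length(size))
  mu <- rep_len(mu, k); size <- rep_len(size, k)
  with_seed(seed, {
    cell <- sample.int(k, n_draws, replace = TRUE)
    x <- stats::rnbinom(n_draws, mu = mu[cell], size = size[cell])
    blocks <- split(x, rep(1:10, length.out = n_draws))
    hb <- vapply(blocks, function(b) {
      p <- as.numeric(table(b)) / length(b)
      -sum(p * log(p)) + (length(p) - 1) / (2 * length(b))
    }, numeric(1))
    p <- as.numeric(table(x)) / n_draws
    list(value = -sum(p * log(p)) + (length(p) - 1) / (2 * n_draws),
         se = stats::sd(hb) / sqrt(10))
  })
}
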