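#' Read and validate a declarative run configuration
#'
#' One YAML file drives the workflow commands ([run_simulate()],
#' [run_entropy_profile()], [run_delta()], [run_compare()]). Top-level keys:
#' `seed`, `out_dir`, and per-command blocks `simulate`, `inputs`, `qc`,
#' `window`, `estimator`, `pathways`, `compare`. Unknown top-level keys are
#' rejected so typos fail fast, before any compute.
#'
#' @param path YAML file path.
#' @return the validated configuration list (class `"run_config"`), with the
#'   config hash attached as attribute `"hash"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "simulate", "inputs", "qc", "window",
             "estimator", "pathways", "compare")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop_config("unknown config field(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop_config("field 'seed' must be a single number")
  if (!is.null(cfg$window)) {
    bad <- setdiff(names(cfg$window), c("window_size", "step"))
    if (length(bad)) stop_config("unknown window field(s): ",
                                 paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$estimator) &&
      !cfg$estimator %in% c("bub", "plugin", "miller_madow", "jackknife"))
    stop_config("field 'estimator' must be one of bub/plugin/miller_madow/",
                "jackknife")
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# md5 of the canonicalised YAML rendering of the config.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  attributes(cfg) <- list(names = names(cfg))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

run_meta <- function(cfg, ...) {
  c(seed = cfg$seed, config_hash = attr(cfg, "hash"), ...)
}

need_out_dir <- function(cfg) {
  if (is.null(cfg$out_dir)) stop_config("field 'out_dir' is required")
  cfg$out_dir
}

log_msg <- function(level, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

#' Generate a synthetic dataset on disk
#'
#' Wraps the generators behind a config block
#' `simulate: {kind: trajectory | pathway_set | two_group, ...overrides}`;
#' overrides are passed to the matching `*_config()` constructor. Writes
#' Matrix Market triplets (so simulated runs exercise the real input path),
#' annotation/pseudotime/ground-truth TSVs and a `manifest.yaml` recording
#' the seed, config hash and file checksums.
#'
#' @param config a [read_run_config()] result or YAML path.
#' @return output directory, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  sim <- cfg$simulate
  if (is.null(sim$kind) ||
      !sim$kind %in% c("trajectory", "pathway_set", "two_group"))
    stop_config("simulate.kind must be trajectory, pathway_set or two_group")
  out <- need_out_dir(cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  args <- sim[setdiff(names(sim), c("kind", "n_pathways"))]
  args$seed <- cfg$seed
  write_one <- function(ds, sub) {
    d <- file.path(out, sub)
    write_matrix_market_triplet(ds$matrix, d)
    utils::write.table(ds$annotation, file.path(d, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ds$pseudotime, file.path(d, "pseudotime.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  }
  dirs <- switch(sim$kind,
    trajectory = {
      ds <- simulate_trajectory(do.call(trajectory_config, args))
      gt <- data.frame(gene_id = ds$ground_truth$gene_ids,
                       gene_class = ds$ground_truth$gene_class,
                       t0 = ds$ground_truth$t0)
      utils::write.table(gt, file.path(out, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_one(ds, ".")
    },
    pathway_set = {
      np <- if (is.null(sim$n_pathways)) 3L else as.integer(sim$n_pathways)
      ps <- simulate_pathway_set(np, do.call(trajectory_config, args))
      vapply(names(ps), function(nm) write_one(ps[[nm]], nm), character(1))
    },
    two_group = {
      tg <- simulate_two_group_hsc(do.call(two_group_config, args))
      da <- file.path(out, "control"); db <- file.path(out, "case")
      write_matrix_market_triplet(tg$control, da)
      write_matrix_market_triplet(tg$case, db)
      c(da, db)
    })
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.yaml"]
  manifest <- list(seed = cfg$seed, kind = sim$kind,
                   config_hash = attr(cfg, "hash"),
                   checksums = as.list(stats::setNames(
                     unname(tools::md5sum(files)),
                     sub(paste0("^", out, "/?"), "", files))))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  log_msg("INFO", "simulated '", sim$kind, "' dataset in ", out)
  invisible(out)
}

read_counts_input <- function(inputs) {
  if (is.null(inputs$counts)) stop_config("inputs.counts is required")
  if (dir.exists(inputs$counts)) read_matrix_market_triplet(inputs$counts)
  else read_dense_table(inputs$counts,
                        orientation = inputs$orientation %||% "genes_in_rows")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' QC, order and profile every configured pathway
#'
#' For each pathway block (`pathways: [{name, labels}, ...]`), applies
#' [qc_filter_cells()], builds the pseudotime ordering and writes the
#' sliding-window profile (`<name>_profile.tsv`), the genes x windows
#' entropy and mean-expression matrices (`<name>_entropy.tsv`,
#' `<name>_meanexpr.tsv`) and a combined `peak_summary.tsv`. Pathways with
#' fewer cells than one window are skipped with a warning; the call fails
#' only if every pathway fails.
#'
#' @param config a [read_run_config()] result or YAML path.
#' @return data.frame of per-pathway peak summaries, invisibly.
#' @export
run_entropy_profile <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$pathways)) stop_config("field 'pathways' is required")
  need_out_dir(cfg)
  mat <- read_counts_input(cfg$inputs)
  ann <- read_cell_annotation(file.path0(cfg$inputs$annotation))
  pt <- read_pseudotime_table(file.path0(cfg$inputs$pseudotime))
  if (!is.null(cfg$qc)) mat <- qc_filter_cells(mat, do.call(qc_config, cfg$qc))
  wspec <- do.call(window_spec, cfg$window %||% list())
  estimator <- cfg$estimator %||% "bub"
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- bub_cache()
  peaks <- list()
  for (pw in cfg$pathways) {
    name <- pw$name
    res <- tryCatch({
      ord <- build_ordering(mat, ann, pt,
                            pathway_spec(name, unlist(pw$labels)))
      log_msg("INFO", "pathway '", name, "': ", length(ord$cell_ids),
              " cells ordered")
      prof <- window_profiles(ord, mat, wspec, estimator, cache)
      meta <- run_meta(cfg)
      write_profile_tsv(prof, file.path(cfg$out_dir,
                                        paste0(name, "_profile.tsv")), meta)
      write_tsv_header(data.frame(gene_id = rownames(prof$entropy),
                                  prof$entropy, check.names = FALSE),
                       file.path(cfg$out_dir, paste0(name, "_entropy.tsv")),
                       c(pathway = name, meta))
      write_tsv_header(data.frame(gene_id = rownames(prof$mean_expr),
                                  prof$mean_expr, check.names = FALSE),
                       file.path(cfg$out_dir, paste0(name, "_meanexpr.tsv")),
                       c(pathway = name, meta))
      pk <- peak_summary(prof)
      data.frame(pathway = name, n_windows = length(prof$mean_entropy),
                 argmax = pk$argmax, label = pk$label,
                 is_transient = pk$is_transient)
    }, icentropy_data_error = function(e) {
      warning("pathway '", name, "' skipped: ", conditionMessage(e))
      NULL
    })
    peaks[[name]] <- res
  }
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks)) stop_data("every pathway failed")
  write_tsv_header(peaks, file.path(cfg$out_dir, "peak_summary.tsv"),
                   run_meta(cfg, estimator = estimator))
  invisible(peaks)
}

file.path0 <- function(p) {
  if (is.null(p)) stop_config("a required input path is missing")
  p
}

# Rebuild a minimal profile object from the matrices run_entropy_profile
# wrote, enough for compute_deltas().
read_profile_matrices <- function(dir, pathway) {
  ef <- file.path(dir, paste0(pathway, "_entropy.tsv"))
  xf <- file.path(dir, paste0(pathway, "_meanexpr.tsv"))
  if (!file.exists(ef) || !file.exists(xf))
    stop_config("profile matrices for pathway '", pathway, "' not found in ",
                dir)
  as_mat <- function(f) {
    df <- read_tsv_header(f)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  structure(list(pathway = pathway, entropy = as_mat(ef),
                 mean_expr = as_mat(xf)),
            class = "window_profiles")
}

#' Delta analysis over previously written pathway profiles
#'
#' Reads the per-pathway matrices produced by [run_entropy_profile()] from
#' `out_dir`, computes delta tables, top-k lists (both keys), the
#' cross-pathway overlap and the delta correlation, and writes them as TSV.
#' With a single pathway the overlap is skipped with a warning.
#'
#' @param config a [read_run_config()] result or YAML path; pathway names
#'   are taken from its `pathways` block.
#' @param k list length for the top-k lists (default 20).
#' @return list with `deltas`, `top_entropy`, `top_expression`, `overlaps`
#'   (or NULL), `correlation` (per pathway), invisibly.
#' @export
run_delta <- function(config, k = 20L) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$pathways)) stop_config("field 'pathways' is required")
  need_out_dir(cfg)
  names_pw <- vapply(cfg$pathways, `[[`, character(1), "name")
  meta <- run_meta(cfg)
  profs <- lapply(names_pw, read_profile_matrices, dir = cfg$out_dir)
  deltas <- lapply(profs, compute_deltas)
  top_e <- lapply(deltas, top_k, key = "delta_entropy", k = k)
  top_x <- lapply(deltas, top_k, key = "delta_expression", k = k)
  for (i in seq_along(names_pw)) {
    write_delta_tsv(deltas[[i]],
                    file.path(cfg$out_dir, paste0(names_pw[i], "_delta.tsv")),
                    meta)
  }
  corr <- lapply(deltas, delta_correlation)
  write_tsv_header(
    data.frame(pathway = names_pw,
               r = vapply(corr, `[[`, numeric(1), "r"),
               p = vapply(corr, `[[`, numeric(1), "p"),
               n = vapply(corr, `[[`, numeric(1), "n"),
               method = vapply(corr, `[[`, character(1), "method")),
    file.path(cfg$out_dir, "delta_correlation.tsv"),
    c(meta, log_transform = "TRUE"))
  overlaps <- NULL
  if (length(names_pw) >= 2L) {
    ov_e <- overlap_lists(top_e); ov_x <- overlap_lists(top_x)
    write_overlap_tsv(ov_e, file.path(cfg$out_dir, "overlap_entropy.tsv"),
                      c(meta, key = "delta_entropy"))
    write_overlap_tsv(ov_x, file.path(cfg$out_dir, "overlap_expression.tsv"),
                      c(meta, key = "delta_expression"))
    overlaps <- list(entropy = ov_e, expression = ov_x)
  } else {
    warning("single pathway: overlap analysis skipped")
  }
  invisible(list(deltas = deltas, top_entropy = top_e,
                 top_expression = top_x, overlaps = overlaps,
                 correlation = corr))
}

#' Subsampled two-sample entropy comparison from a config
#'
#' Config block `compare: {sample_a, sample_b, n_subsamples, subsample_size,
#' test_variant, dissociation_a, dissociation_b}`. The optional dissociation
#' gene lists are intersected ([dissociation_gene_set()]) and excluded from
#' both samples. Writes the per-subsample table and tier tally
#' ([write_comparison_tsv()]) and logs the tally.
#'
#' @param config a [read_run_config()] result or YAML path.
#' @return the [hsc_entropy_comparison()] result, invisibly.
#' @export
run_compare <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  cp <- cfg$compare
  if (is.null(cp$sample_a) || is.null(cp$sample_b))
    stop_config("compare.sample_a and compare.sample_b are required")
  read_one <- function(p) if (dir.exists(p)) read_matrix_market_triplet(p)
                          else read_dense_table(p)
  a <- read_one(cp$sample_a); b <- read_one(cp$sample_b)
  excl <- character()
  if (!is.null(cp$dissociation_a) && !is.null(cp$dissociation_b))
    excl <- dissociation_gene_set(read_gene_list(cp$dissociation_a),
                                  read_gene_list(cp$dissociation_b))
  ccfg <- comparison_config(
    n_subsamples = cp$n_subsamples %||% 100L,
    subsample_size = cp$subsample_size %||% 700L,
    test_variant = cp$test_variant %||% "rank_sum",
    exclude_genes = excl, seed = cfg$seed)
  res <- hsc_entropy_comparison(a, b, ccfg)
  dir.create(need_out_dir(cfg), showWarnings = FALSE, recursive = TRUE)
  write_comparison_tsv(res,
                       file.path(cfg$out_dir, "comparison_subsamples.tsv"),
                       file.path(cfg$out_dir, "comparison_tiers.tsv"),
                       run_meta(cfg))
  log_msg("INFO", "tier tally: ",
          paste(names(res$tier_tally), res$tier_tally, sep = "=",
                collapse = ", "))
  invisible(res)
}
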