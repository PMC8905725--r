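#' Consensus dissociation gene set
#'
#' Mechanical tissue dissociation induces a stress-response signature that
#' inflates apparent cell-to-cell variability; when comparing samples with
#' different dissociation protocols those genes are excluded. The excluded
#' set is the intersection of two published dissociation signatures,
#' case-normalised on gene symbols.
#'
#' @param signature_a,signature_b non-empty character vectors of gene
#'   symbols.
#' @return sorted character vector (upper-cased symbols); empty with a
#'   warning when the signatures do not intersect.
#' @export
dissociation_gene_set <- function(signature_a, signature_b) {
  if (!length(signature_a) || !length(signature_b))
    stop_config("both signatures must be non-empty")
  out <- sort(intersect(toupper(signature_a), toupper(signature_b)))
  if (!length(out)) warning("dissociation signatures do not intersect")
  out
}

#' Equalise per-cell-type cell numbers across samples
#'
#' For each cell type, every sample is downsampled without replacement to
#' the minimum count of that type across samples, so between-sample entropy
#' comparisons are not confounded by cell numbers. Types absent from any
#' sample are dropped from all samples, with a warning.
#'
#' @param samples named list; each element either a cell-annotation
#'   data.frame (columns `cell_id`, `population_label`) or a list with an
#'   `annotation` element of that shape.
#' @param seed RNG seed making the draw deterministic.
#' @return named list of character vectors (retained cell ids per sample),
#'   with attribute `"sizes"` (type x sample matrix of retained counts).
#' @export
equalize_celltypes <- function(samples, seed = 1L) {
  if (length(samples) < 2L) stop_config("need at least 2 samples")
  anns <- lapply(samples, function(s)
    if (is.data.frame(s)) s else s$annotation)
  types <- lapply(anns, function(a) table(a$population_label))
  all_types <- sort(unique(unlist(lapply(types, names))))
  counts <- vapply(types, function(tt)
    ifelse(all_types %in% names(tt), as.integer(tt[all_types]), 0L),
    integer(length(all_types)))
  counts <- matrix(counts, nrow = length(all_types),
                   dimnames = list(all_types, names(samples)))
  mins <- apply(counts, 1L, min)
  if (any(mins == 0L)) {
    warning("cell type(s) absent from >= 1 sample dropped from all: ",
            paste(all_types[mins == 0L], collapse = ", "))
  }
  keep_types <- all_types[mins > 0L]
  if (!length(keep_types)) stop_data("no cell type shared by all samples")
  with_seed(seed, {
    out <- lapply(anns, function(a) {
      picked <- unlist(lapply(keep_types, function(ty) {
        ids <- sort(a$cell_id[a$population_label == ty])
        sample(ids, mins[ty])
      }), use.names = FALSE)
      picked
    })
    names(out) <- names(samples)
    attr(out, "sizes") <- counts[keep_types, , drop = FALSE] * 0L + mins[keep_types]
    out
  })
}

#' Configuration for the subsampled entropy comparison
#'
#' @param n_subsamples number of repeated subsample draws (default 100).
#' @param subsample_size cells drawn per sample per iteration (default 700).
#' @param significance_tiers strictly decreasing p-value thresholds
#'   (default 0.05, 0.01, 0.001, 0.0001).
#' @param test_variant `"rank_sum"` (default; two-sided Wilcoxon rank-sum on
#'   the two per-gene entropy vectors) or `"signed_rank_paired_by_gene"`
#'   (two-sided Wilcoxon signed-rank on per-gene entropy differences). The
#'   variant used is stamped into the result.
#' @param exclude_genes gene ids/symbols removed from both samples before
#'   the comparison (e.g. [dissociation_gene_set()]).
#' @param seed base seed; iteration `i` draws from a seed stream derived
#'   from it, so runs are reproducible and iterations independent.
#' @param keep_gene_entropies retain the per-gene entropy matrix of every
#'   subsample (memory-hungry; default FALSE).
#' @param mirror_subsamples diagnostic switch: when TRUE, sample B reuses
#'   sample A's subsample indices (meaningful only for self-comparisons).
#' @return an object of class `"comparison_config"`.
#' @export
comparison_config <- function(n_subsamples = 100L, subsample_size = 700L,
                              significance_tiers = c(0.05, 0.01, 0.001,
                                                     0.0001),
                              test_variant = c("rank_sum",
                                               "signed_rank_paired_by_gene"),
                              exclude_genes = character(),
                              seed = 1L, keep_gene_entropies = FALSE,
                              mirror_subsamples = FALSE) {
  test_variant <- match.arg(test_variant)
  if (subsample_size < 2L) stop_config("subsample_size must be >= 2")
  if (length(significance_tiers) < 1L ||
      any(diff(significance_tiers) >= 0))
    stop_config("significance_tiers must be strictly decreasing")
  structure(list(n_subsamples = as.integer(n_subsamples),
                 subsample_size = as.integer(subsample_size),
                 significance_tiers = significance_tiers,
                 test_variant = test_variant,
                 exclude_genes = exclude_genes,
                 seed = as.integer(seed),
                 keep_gene_entropies = keep_gene_entropies,
                 mirror_subsamples = mirror_subsamples),
            class = "comparison_config")
}

#' Subsampled intercellular-entropy comparison of two cell populations
#'
#' The root-compartment contrast: repeatedly draw equal-size cell subsamples
#' from each sample, compute per-gene intercellular entropy over each whole
#' subsample (one window of `subsample_size` cells, BUB estimator), record
#' the mean entropy over genes per sample, and compare the two per-gene
#' entropy vectors with the configured two-sided Wilcoxon variant. The
#' p-values are tallied against the significance tiers.
#'
#' @param sample_a,sample_b `"count_matrix"` objects restricted to the cell
#'   population under comparison (e.g. HSCs); gene sets are aligned to their
#'   intersection.
#' @param config a [comparison_config()].
#' @param cache a [bub_cache()] shared across iterations (created if
#'   omitted); coefficient solving is keyed on `(subsample_size, m)` so each
#'   distinct bin count is solved once.
#' @return an object of class `"entropy_comparison"`: list with
#'   `subsamples` (data.frame: `iter`, `mean_entropy_a`, `mean_entropy_b`,
#'   `p`), `tier_tally` (named counts of subsamples with p below each tier),
#'   `config`, `n_genes`, and optionally `gene_entropies`.
#' @export
hsc_entropy_comparison <- function(sample_a, sample_b,
                                   config = comparison_config(),
                                   cache = NULL) {
  sample_a <- as_count_matrix(sample_a)
  sample_b <- as_count_matrix(sample_b)
  genes <- intersect(sample_a$gene_ids, sample_b$gene_ids)
  genes <- setdiff(genes, toupper(config$exclude_genes))
  genes <- setdiff(genes, config$exclude_genes)
  if (!length(genes)) stop_data("no shared genes after exclusions")
  ss <- config$subsample_size
  if (ncol(sample_a$counts) < ss || ncol(sample_b$counts) < ss)
    stop_data("each sample needs >= ", ss, " cells (have ",
              ncol(sample_a$counts), " and ", ncol(sample_b$counts), ")")
  A <- as.matrix(sample_a$counts[match(genes, sample_a$gene_ids), ,
                                 drop = FALSE])
  B <- as.matrix(sample_b$counts[match(genes, sample_b$gene_ids), ,
                                 drop = FALSE])
  storage.mode(A) <- "integer"; storage.mode(B) <- "integer"
  if (all(A == 0L) && all(B == 0L)) stop_data("all-zero matrices")
  if (is.null(cache)) cache <- bub_cache()
  n <- config$n_subsamples
  mean_a <- mean_b <- pvals <- numeric(n)
  kept <- if (config$keep_gene_entropies) vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    ia <- sample.int(ncol(A), ss)
    ib <- if (config$mirror_subsamples) ia else sample.int(ncol(B), ss)
    ea <- window_entropy_vec(A[, ia, drop = FALSE], "bub", cache)
    eb <- window_entropy_vec(B[, ib, drop = FALSE], "bub", cache)
    mean_a[i] <- mean(ea); mean_b[i] <- mean(eb)
    pvals[i] <- wilcoxon_p(ea, eb, config$test_variant)
    if (config$keep_gene_entropies)
      kept[[i]] <- cbind(a = ea, b = eb)
  }
  tally <- vapply(config$significance_tiers,
                  function(t) sum(pvals < t), integer(1))
  names(tally) <- paste0("p<", config$significance_tiers)
  structure(list(subsamples = data.frame(iter = seq_len(n),
                                         mean_entropy_a = mean_a,
                                         mean_entropy_b = mean_b,
                                         p = pvals),
                 tier_tally = tally, config = config,
                 n_genes = length(genes),
                 gene_entropies = kept),
            class = "entropy_comparison")
}

wilcoxon_p <- function(ea, eb, variant) {
  if (variant == "signed_rank_paired_by_gene") {
    d <- ea - eb
    if (all(d == 0)) {
      warning("degenerate paired test: all per-gene differences are zero")
      return(1)
    }
    stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  } else {
    if (all(ea == eb)) {
      warning("degenerate rank-sum test: entropy vectors are identical")
      return(1)
    }
    stats::wilcox.test(ea, eb, exact = FALSE, correct = TRUE)$p.value
  }
}

#' @export
print.entropy_comparison <- function(x, ...) {
  cat(sprintf(paste0("entropy_comparison: %d subsamples of %d cells, ",
                     "%d genes, %s test\n"),
              nrow(x$subsamples), x$config$subsample_size, x$n_genes,
              x$config$test_variant))
  cat(sprintf("  mean entropy A %.4f, B %.4f (averaged over subsamples)\n",
              mean(x$subsamples$mean_entropy_a),
              mean(x$subsamples$mean_entropy_b)))
  cat("  significance tier tally:\n")
  print(x$tier_tally)
  invisible(x)
}

#' Export a comparison result as two TSVs
#'
#' Writes the per-subsample table and the tier tally, both with the
#' configuration echoed in the header.
#'
#' @param x an [hsc_entropy_comparison()] result.
#' @param subsample_path,tally_path output paths.
#' @param meta extra header metadata.
#' @return invisibly, the two paths.
#' @export
write_comparison_tsv <- function(x, subsample_path, tally_path,
                                 meta = character()) {
  hdr <- c(test_variant = x$config$test_variant,
           n_subsamples = x$config$n_subsamples,
           subsample_size = x$config$subsample_size,
           seed = x$config$seed,
           n_genes = x$n_genes,
           n_excluded_genes = length(x$config$exclude_genes),
           meta)
  write_tsv_header(x$subsamples, subsample_path, hdr)
  write_tsv_header(data.frame(tier = names(x$tier_tally),
                              count = unname(x$tier_tally)),
                   tally_path, hdr)
  invisible(c(subsample_path, tally_path))
}
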