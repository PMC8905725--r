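#' Per-gene delta-entropy and delta-expression
#'
#' For one pathway profile, delta-entropy is the difference between the
#' maximum and the minimum intercellular entropy a gene reaches across the
#' sliding windows, and delta-expression is the max - min of its window mean
#' raw expression. Genes with large delta-entropy change how variable they
#' are during differentiation; genes with large delta-expression change how
#' much they are expressed.
#'
#' @param series a [window_profiles()] result with at least 2 windows.
#' @return data.frame of class `"delta_table"` with columns `gene_id`,
#'   `delta_entropy`, `delta_expression`, `pathway` (one row per gene).
#' @export
compute_deltas <- function(series) {
  if (ncol(series$entropy) < 2L)
    stop_data("deltas need at least 2 windows")
  rng_e <- apply(series$entropy, 1L, range)
  rng_x <- apply(series$mean_expr, 1L, range)
  out <- data.frame(gene_id = rownames(series$entropy),
                    delta_entropy = rng_e[2L, ] - rng_e[1L, ],
                    delta_expression = rng_x[2L, ] - rng_x[1L, ],
                    pathway = series$pathway,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Top-k genes by delta-entropy or delta-expression
#'
#' Descending by the chosen key; ties are broken lexicographically by gene
#' id so the 20-gene lists are reproducible.
#'
#' @param table a [compute_deltas()] result.
#' @param key `"delta_entropy"` or `"delta_expression"`.
#' @param k list length (default 20; truncated to the number of genes).
#' @return an object of class `"top_k_list"`: list with `pathway`, `key`,
#'   `k`, `genes` (ordered character vector) and `values`.
#' @export
top_k <- function(table, key = c("delta_entropy", "delta_expression"),
                  k = 20L) {
  key <- match.arg(key)
  if (!nrow(table)) stop_data("empty delta table")
  ord <- order(-table[[key]], table$gene_id)
  take <- ord[seq_len(min(k, nrow(table)))]
  structure(list(pathway = table$pathway[1L], key = key, k = as.integer(k),
                 genes = table$gene_id[take], values = table[[key]][take]),
            class = "top_k_list")
}

#' @export
print.top_k_list <- function(x, ...) {
  cat(sprintf("top %d genes by %s in '%s':\n", length(x$genes), x$key,
              x$pathway))
  print(stats::setNames(round(x$values, 4), x$genes))
  invisible(x)
}

#' Overlap structure of per-pathway top-k lists
#'
#' Tallies, for every gene in the union of the lists, how many pathway lists
#' contain it; aggregates genes private to one pathway, shared by at least
#' two, and common to all; and reports per focal pathway how many of its
#' genes reappear in at least one / at least two other lists.
#'
#' @param lists list of [top_k()] results, one per pathway (unique names).
#' @return an object of class `"overlap_summary"`: list with `membership`
#'   (genes x pathways logical matrix), `per_gene` (named pathway counts),
#'   `n_exactly_one`, `n_at_least_two`, `n_all`, and `focal` (data.frame
#'   with per-pathway `in_ge1_other`, `in_ge2_other`).
#' @export
overlap_lists <- function(lists) {
  if (length(lists) < 2L) stop_data("overlap needs at least 2 lists")
  pw <- vapply(lists, function(l) l$pathway, character(1))
  if (anyDuplicated(pw)) stop_data("duplicate pathway names in lists")
  union_genes <- sort(unique(unlist(lapply(lists, `[[`, "genes"))))
  mem <- vapply(lists, function(l) union_genes %in% l$genes,
                logical(length(union_genes)))
  mem <- matrix(mem, nrow = length(union_genes),
                dimnames = list(union_genes, pw))
  per_gene <- rowSums(mem)
  focal <- data.frame(
    pathway = pw,
    in_ge1_other = vapply(seq_along(lists), function(i)
      sum(rowSums(mem[mem[, i], -i, drop = FALSE]) >= 1L), integer(1)),
    in_ge2_other = vapply(seq_along(lists), function(i)
      sum(rowSums(mem[mem[, i], -i, drop = FALSE]) >= 2L), integer(1)),
    row.names = NULL)
  structure(list(membership = mem, per_gene = per_gene,
                 n_exactly_one = sum(per_gene == 1L),
                 n_at_least_two = sum(per_gene >= 2L),
                 n_all = sum(per_gene == length(lists)),
                 focal = focal),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(paste0("overlap of %d lists (%d genes in union): %d private, ",
                     "%d in >= 2 pathways, %d common to all\n"),
              ncol(x$membership), nrow(x$membership), x$n_exactly_one,
              x$n_at_least_two, x$n_all))
  invisible(x)
}

#' Correlation between delta-expression and delta-entropy
#'
#' Both axes are log(1 + x)-transformed by default (the delta distributions
#' are heavy-tailed and are inspected on logarithmic scales); the method
#' used is stamped into the result.
#'
#' @param table a [compute_deltas()] result with >= 3 genes.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_transform apply `log1p` to both deltas first (default TRUE;
#'   irrelevant for Spearman ranks).
#' @return list with `r`, `p` (two-sided), `n`, `method`, `log_transform`.
#' @export
delta_correlation <- function(table, method = c("pearson", "spearman"),
                              log_transform = TRUE) {
  method <- match.arg(method)
  x <- table$delta_expression; y <- table$delta_entropy
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_data("need >= 3 genes with finite deltas")
  if (log_transform) { x <- log1p(x); y <- log1p(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("zero variance on one axis")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method, log_transform = log_transform)
}

#' Transcription factors among the most delta-entropic genes
#'
#' Intersects the `top_n` genes by delta-entropy with a transcription-factor
#' list, preserving delta-entropy order.
#'
#' @param table a [compute_deltas()] result.
#' @param tf_list non-empty character vector of gene ids/symbols.
#' @param top_n delta-entropy rank cut-off (default 1000).
#' @return character vector (possibly empty, with a warning).
#' @export
tf_subset <- function(table, tf_list, top_n = 1000L) {
  if (!length(tf_list)) stop_config("tf_list is empty")
  ord <- order(-table$delta_entropy, table$gene_id)
  top <- table$gene_id[ord[seq_len(min(top_n, nrow(table)))]]
  out <- top[top %in% tf_list]
  if (!length(out))
    warning("no transcription factor in the top ", top_n,
            " delta-entropic genes")
  out
}

#' Export delta analysis results as TSV
#' @param table a [compute_deltas()] result.
#' @param path output path.
#' @param meta extra header metadata.
#' @return `path`, invisibly.
#' @export
write_delta_tsv <- function(table, path, meta = character()) {
  write_tsv_header(as.data.frame(table), path, meta)
}

#' Export an overlap membership matrix as TSV
#'
#' UpSet-style membership table: one row per gene in the union, one 0/1
#' column per pathway plus the pathway count.
#'
#' @param overlap an [overlap_lists()] result.
#' @param path output path.
#' @param meta extra header metadata.
#' @return `path`, invisibly.
#' @export
write_overlap_tsv <- function(overlap, path, meta = character()) {
  df <- data.frame(gene_id = rownames(overlap$membership),
                   overlap$membership * 1L,
                   n_pathways = overlap$per_gene,
                   row.names = NULL, check.names = FALSE)
  write_tsv_header(df, path, meta)
}
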