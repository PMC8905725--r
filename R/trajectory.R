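#' Define a differentiation pathway
#'
#' A pathway is an ordered list of population labels, from the most immature
#' compartment (e.g. `"CD34+ HSC"`) to the most mature state of interest.
#' Membership of the label set selects the cells; ordering within the pathway
#' comes from the pseudotime, not from the label order.
#'
#' @param name pathway name (e.g. `"erythropoiesis"`).
#' @param ordered_labels unique, non-empty character vector of population
#'   labels.
#' @return an object of class `"pathway_spec"`.
#' @export
pathway_spec <- function(name, ordered_labels) {
  ordered_labels <- as.character(ordered_labels)
  if (!length(ordered_labels)) stop_config("ordered_labels is empty")
  if (anyDuplicated(ordered_labels))
    stop_config("ordered_labels must be unique")
  structure(list(name = as.character(name), ordered_labels = ordered_labels),
            class = "pathway_spec")
}

#' Sliding-window geometry
#'
#' @param window_size cells per window (default 50).
#' @param step cells between consecutive window starts (default 10).
#' @return an object of class `"window_spec"`.
#' @export
window_spec <- function(window_size = 50L, step = 10L) {
  window_size <- as.integer(window_size); step <- as.integer(step)
  if (window_size < 2L) stop_config("window_size must be >= 2")
  if (step < 1L || step > window_size)
    stop_config("step must lie in [1, window_size]")
  structure(list(window_size = window_size, step = step),
            class = "window_spec")
}

#' Order a pathway's cells along pseudotime
#'
#' Retains exactly the cells of `matrix` whose population label belongs to
#' the pathway, sorted by ascending pseudotime; ties are broken by
#' lexicographic cell id so orderings are reproducible.
#'
#' @param matrix a `"count_matrix"` (or coercible).
#' @param annotation data.frame with columns `cell_id`, `population_label`
#'   (and optionally `sample_id`), as from [read_cell_annotation()].
#' @param pseudotime data.frame with columns `cell_id`, `pseudotime`, as from
#'   [read_pseudotime_table()].
#' @param pathway a [pathway_spec()].
#' @return an object of class `"trajectory_ordering"`: list with `pathway`,
#'   `cell_ids`, `pseudotimes` (non-decreasing), `labels`.
#' @export
build_ordering <- function(matrix, annotation, pseudotime, pathway) {
  matrix <- as_count_matrix(matrix)
  if (!inherits(pathway, "pathway_spec"))
    stop_config("pathway must be a pathway_spec")
  lab <- annotation$population_label[match(matrix$cell_ids, annotation$cell_id)]
  sel <- which(!is.na(lab) & lab %in% pathway$ordered_labels)
  if (!length(sel))
    stop_data("no cells of pathway '", pathway$name, "' in the matrix")
  ids <- matrix$cell_ids[sel]
  pt <- pseudotime$pseudotime[match(ids, pseudotime$cell_id)]
  if (anyNA(pt))
    stop_data("missing pseudotime for ", sum(is.na(pt)),
              " cell(s) of pathway '", pathway$name, "', e.g. '",
              ids[which(is.na(pt))[1L]], "'")
  ord <- order(pt, ids)
  message(sprintf("pathway '%s': %d cells ordered", pathway$name, length(ids)))
  structure(list(pathway = pathway, cell_ids = ids[ord],
                 pseudotimes = pt[ord], labels = lab[sel][ord]),
            class = "trajectory_ordering")
}

#' @export
print.trajectory_ordering <- function(x, ...) {
  cat(sprintf("trajectory_ordering '%s': %d cells, pseudotime [%.3g, %.3g]\n",
              x$pathway$name, length(x$cell_ids),
              min(x$pseudotimes), max(x$pseudotimes)))
  invisible(x)
}

#' Full sliding-window start positions
#'
#' Windows are full only: starts run `1, 1 + step, 1 + 2*step, ...` giving
#' exactly `floor((n_cells - window_size) / step) + 1` windows; no ragged
#' tail window is emitted.
#'
#' @param n_cells number of ordered cells.
#' @param spec a [window_spec()].
#' @param pathway_name optional name used in the too-few-cells error message.
#' @return integer vector of 1-based start indices; window `w` spans cells
#'   `starts[w] .. starts[w] + window_size - 1`.
#' @export
sliding_windows <- function(n_cells, spec = window_spec(),
                            pathway_name = NULL) {
  n_cells <- as.integer(n_cells)
  if (n_cells < spec$window_size)
    stop_data("pathway ", if (!is.null(pathway_name))
      paste0("'", pathway_name, "' "), "has ", n_cells,
      " cells, fewer than the window size ", spec$window_size)
  n_windows <- (n_cells - spec$window_size) %/% spec$step + 1L
  seq.int(1L, by = spec$step, length.out = n_windows)
}

#' Sliding-window entropy and expression profiles
#'
#' For every gene and every full window along the ordering, computes the
#' intercellular entropy of the gene's raw counts over the window's cells
#' (BUB by default, bin count = largest count + 1) and the arithmetic mean
#' raw count. The per-window mean entropy averages over the full gene set of
#' the matrix — including genes that are all-zero in a window (entropy 0) —
#' so the profile is comparable across windows regardless of how many genes
#' are detected locally.
#'
#' @param ordering a [build_ordering()] result.
#' @param matrix the `"count_matrix"` the ordering was built from.
#' @param spec a [window_spec()].
#' @param estimator `"bub"` (default), `"plugin"`, `"miller_madow"` or
#'   `"jackknife"`.
#' @param cache a [bub_cache()] reused across calls; created if omitted.
#' @param downsample_depth experimental extension, off by default: when TRUE
#'   each window's cells are binomially thinned to the window's minimum
#'   library size before entropy estimation. The standard analysis runs on
#'   raw counts without depth adjustment.
#' @param seed RNG seed used only when `downsample_depth = TRUE`.
#' @return an object of class `"window_profiles"`: list with `pathway`,
#'   `estimator`, `spec`, `window_starts`, `first_cell_label`,
#'   `first_cell_pseudotime`, `entropy` (genes x windows, nats),
#'   `mean_expr` (genes x windows, raw counts) and `mean_entropy`
#'   (per-window mean over all genes).
#' @export
window_profiles <- function(ordering, matrix, spec = window_spec(),
                            estimator = c("bub", "plugin", "miller_madow",
                                          "jackknife"),
                            cache = NULL, downsample_depth = FALSE,
                            seed = 1L) {
  estimator <- match.arg(estimator)
  matrix <- as_count_matrix(matrix)
  if (!inherits(ordering, "trajectory_ordering"))
    stop_config("ordering must be a trajectory_ordering")
  pos <- match(ordering$cell_ids, matrix$cell_ids)
  if (anyNA(pos))
    stop_data("ordering contains cells absent from the matrix")
  starts <- sliding_windows(length(pos), spec, ordering$pathway$name)
  if (is.null(cache)) cache <- bub_cache()
  M <- as.matrix(matrix$counts[, pos, drop = FALSE])
  storage.mode(M) <- "integer"
  G <- nrow(M); W <- length(starts)
  ent <- matrix(0, G, W, dimnames = list(matrix$gene_ids, NULL))
  mexp <- matrix(0, G, W, dimnames = list(matrix$gene_ids, NULL))
  ws <- spec$window_size
  if (downsample_depth) set.seed(seed)
  for (w in seq_len(W)) {
    idx <- starts[w]:(starts[w] + ws - 1L)
    sub <- M[, idx, drop = FALSE]
    if (downsample_depth) {
      depth <- colSums(sub)
      target <- min(depth[depth > 0], Inf)
      for (cidx in which(depth > target))
        sub[, cidx] <- stats::rbinom(G, sub[, cidx], target / depth[cidx])
    }
    mexp[, w] <- rowMeans(sub)
    ent[, w] <- window_entropy_vec(sub, estimator, cache)
  }
  structure(list(pathway = ordering$pathway$name, estimator = estimator,
                 spec = spec, window_starts = starts,
                 first_cell_label = ordering$labels[starts],
                 first_cell_pseudotime = ordering$pseudotimes[starts],
                 entropy = ent, mean_expr = mexp,
                 mean_entropy = colMeans(ent)),
            class = "window_profiles")
}

# Entropy of every row of an integer genes x N window matrix. The BUB/plugin
# paths use the identity  sum_j a_j h_j = sum_levels a_{c(level)}  to skip
# building the occupancy vector explicitly.
window_entropy_vec <- function(sub, estimator, cache) {
  N <- ncol(sub); G <- nrow(sub)
  out <- numeric(G)
  for (g in seq_len(G)) {
    v <- sub[g, ]
    mx <- max(v)
    if (mx == 0L) next                         # all-zero gene: entropy 0
    lc <- tabulate(v + 1L, nbins = mx + 1L)    # cells per expression level
    out[g] <- switch(estimator,
      bub = {
        a <- cache_get(cache, N, mx + 1L)$a
        sum(a[lc + 1L])
      },
      plugin = {
        p <- lc[lc > 0L] / N
        -sum(p * log(p))
      },
      miller_madow = {
        p <- lc[lc > 0L] / N
        -sum(p * log(p)) + (sum(lc > 0L) - 1) / (2 * N)
      },
      jackknife = jackknife_entropy(v))
  }
  out
}

#' @export
print.window_profiles <- function(x, ...) {
  cat(sprintf(paste0("window_profiles '%s': %d genes x %d windows ",
                     "(size %d, step %d, %s estimator)\n"),
              x$pathway, nrow(x$entropy), ncol(x$entropy),
              x$spec$window_size, x$spec$step, x$estimator))
  cat(sprintf("  mean entropy range [%.4f, %.4f] nats\n",
              min(x$mean_entropy), max(x$mean_entropy)))
  invisible(x)
}

#' @export
summary.window_profiles <- function(object, ...) {
  data.frame(window = seq_along(object$window_starts),
             start = object$window_starts,
             pseudotime = object$first_cell_pseudotime,
             first_cell_label = object$first_cell_label,
             mean_entropy = object$mean_entropy)
}

#' Plot the mean-entropy profile of a trajectory
#'
#' One point per window, positioned at the first cell's pseudotime and
#' coloured by the first cell's population label.
#'
#' @param x a [window_profiles()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.window_profiles <- function(x, ...) {
  labs <- factor(x$first_cell_label, levels = unique(x$first_cell_label))
  cols <- grDevices::hcl.colors(max(2L, nlevels(labs)), "Dark 3")
  graphics::plot(x$first_cell_pseudotime, x$mean_entropy,
                 col = cols[as.integer(labs)], pch = 19,
                 xlab = "pseudotime (first cell of window)",
                 ylab = "mean intercellular entropy (nats)",
                 main = x$pathway, ...)
  graphics::legend("topright", legend = levels(labs), bty = "n",
                   col = cols[seq_len(nlevels(labs))], pch = 19, cex = 0.8)
  invisible(x)
}

#' Locate the entropy peak of a profile
#'
#' @param series a [window_profiles()] result with at least 3 windows.
#' @return list with `argmax` (window index, earliest on ties), `label`
#'   (first-cell label at the argmax) and `is_transient` (`TRUE` when the
#'   peak strictly exceeds both the first and the last window's mean
#'   entropy).
#' @export
peak_summary <- function(series) {
  me <- series$mean_entropy
  if (length(me) < 3L) stop_data("peak_summary needs at least 3 windows")
  argmax <- which.max(me)              # earliest window on ties
  list(argmax = argmax,
       label = series$first_cell_label[argmax],
       is_transient = me[argmax] > me[1L] && me[argmax] > me[length(me)])
}

#' Export a window profile as TSV
#'
#' One row per window (start index, first-cell pseudotime and label, mean
#' entropy) with a reproducibility header.
#'
#' @param x a [window_profiles()] result.
#' @param path output path.
#' @param meta extra header metadata (named character).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, meta = character()) {
  write_tsv_header(summary(x), path,
                   c(pathway = x$pathway, estimator = x$estimator,
                     window_size = x$spec$window_size, step = x$spec$step,
                     meta))
}
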