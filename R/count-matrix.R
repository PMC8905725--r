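#' Construct a validated gene x cell count matrix
#'
#' The substrate of every analysis in this package is a genes-by-cells matrix
#' of raw (non-normalised) integer counts: intercellular entropy is computed
#' directly on the raw counts. The constructor validates integrality,
#' non-negativity and identifier uniqueness, and stores the counts sparsely.
#'
#' @param counts genes x cells numeric matrix (base or `Matrix`), integer
#'   valued and non-negative.
#' @param gene_ids,cell_ids unique identifiers; default to the dimnames.
#' @param gene_symbols optional gene symbols parallel to `gene_ids` (the id
#'   column stays authoritative; symbols are display/QC metadata). Duplicate
#'   symbols are disambiguated by suffixing, with a warning.
#' @return an object of class `"count_matrix"` with elements `counts`
#'   (a `dgCMatrix` carrying dimnames), `gene_ids`, `cell_ids`,
#'   `gene_symbols`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts), gene_symbols = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop_config("gene and cell identifiers are required")
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids))
    stop_data("dimension mismatch: counts are ", nrow(counts), " x ",
              ncol(counts), " but ", length(gene_ids), " gene and ",
              length(cell_ids), " cell ids were given")
  if (anyDuplicated(gene_ids))
    stop_data("duplicate gene ids: ",
              paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop_data("duplicate cell ids: ",
              paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  m <- if (methods::is(counts, "Matrix")) {
    methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  } else {
    methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                "generalMatrix")
  }
  v <- m@x
  if (length(v)) {
    if (anyNA(v)) stop_data("counts contain missing values")
    if (any(v < 0) || any(v != round(v))) {
      tm <- methods::as(m, "TsparseMatrix")
      bad <- which(tm@x < 0 | tm@x != round(tm@x))[1L]
      what <- if (tm@x[bad] < 0) "negative" else "non-integer"
      stop_data(what, " count at gene '", gene_ids[tm@i[bad] + 1L],
                "', cell '", cell_ids[tm@j[bad] + 1L], "'")
    }
  }
  dimnames(m) <- list(gene_ids, cell_ids)
  if (!is.null(gene_symbols)) {
    gene_symbols <- as.character(gene_symbols)
    if (length(gene_symbols) != length(gene_ids))
      stop_data("gene_symbols length does not match gene_ids")
    if (anyDuplicated(gene_symbols)) {
      warning("duplicate gene symbols disambiguated by suffixing")
      gene_symbols <- make.unique(gene_symbols, sep = ".")
    }
  }
  structure(list(counts = m, gene_ids = gene_ids, cell_ids = cell_ids,
                 gene_symbols = gene_symbols),
            class = "count_matrix")
}

#' Coerce to a count matrix
#' @param x a `count_matrix`, base matrix or `Matrix` with dimnames.
#' @return a `"count_matrix"`.
#' @export
as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  m <- x$counts[i, j, drop = FALSE]
  sym <- x$gene_symbols
  if (!is.null(sym)) sym <- sym[match(rownames(m), x$gene_ids)]
  count_matrix(m, gene_symbols = sym)
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx` (coordinate integer format, genes in rows),
#' `barcodes.tsv` (one cell barcode per line) and `features.tsv`
#' (id, optionally symbol and type, tab-separated, no header) in `dir_path`.
#' The features id column is the authoritative gene identifier; symbols are
#' retained as metadata.
#'
#' @param dir_path directory holding the three files.
#' @return a `"count_matrix"`.
#' @export
read_matrix_market_triplet <- function(dir_path) {
  paths <- file.path(dir_path, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_config("missing file(s): ", paste(missing, collapse = ", "))
  m <- Matrix::readMM(paths[1L])
  barcodes <- readLines(paths[2L])
  feat <- utils::read.table(paths[3L], sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  if (nrow(feat) != nrow(m))
    stop_data("matrix.mtx declares ", nrow(m), " genes but features.tsv has ",
              nrow(feat), " lines")
  if (length(barcodes) != ncol(m))
    stop_data("matrix.mtx declares ", ncol(m), " cells but barcodes.tsv has ",
              length(barcodes), " lines")
  count_matrix(m, gene_ids = feat[[1L]], cell_ids = barcodes,
               gene_symbols = if (ncol(feat) >= 2L) feat[[2L]])
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' Inverse of [read_matrix_market_triplet()]; the synthetic-data workflows
#' write through this so simulated runs exercise the real input path.
#'
#' @param x a `"count_matrix"`.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_matrix_market_triplet <- function(x, dir_path) {
  x <- as_count_matrix(x)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir_path, "matrix.mtx"))
  writeLines(x$cell_ids, file.path(dir_path, "barcodes.tsv"))
  sym <- if (is.null(x$gene_symbols)) x$gene_ids else x$gene_symbols
  utils::write.table(
    data.frame(x$gene_ids, sym, "Gene Expression"),
    file.path(dir_path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}

#' Read a dense count table (TSV/CSV, optionally gzipped)
#'
#' @param path file path; `.csv`/`.csv.gz` parsed comma-separated, otherwise
#'   tab-separated. First column and header row carry identifiers.
#' @param orientation `"genes_in_rows"` (default) or `"cells_in_rows"`.
#' @return a `"count_matrix"` normalised to genes x cells.
#' @export
read_dense_table <- function(path,
                             orientation = c("genes_in_rows", "cells_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_config("no such file: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_data("non-numeric entries in ", path)
  if (orientation == "cells_in_rows") m <- t(m)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_data("invalid count at gene '", rownames(m)[bad[1L, 1L]],
              "', cell '", colnames(m)[bad[1L, 2L]], "'")
  count_matrix(m)
}

#' Write a count matrix as a dense TSV
#' @param x a `"count_matrix"`.
#' @param path output path (`.gz` suffix compresses).
#' @param orientation as in [read_dense_table()].
#' @return `path`, invisibly.
#' @export
write_dense_table <- function(x,
                              path,
                              orientation = c("genes_in_rows",
                                              "cells_in_rows")) {
  orientation <- match.arg(orientation)
  x <- as_count_matrix(x)
  m <- as.matrix(x$counts)
  if (orientation == "cells_in_rows") m <- t(m)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  utils::write.table(as.data.frame(m), con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a cell annotation table
#'
#' Tab-separated with header; columns `cell_id`, `population_label`,
#' `sample_id`. Annotation is an input here (e.g. produced upstream by a
#' reference-based classifier), never recomputed.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_cell_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("cell_id", "population_label", "sample_id")
  if (!all(need %in% names(df)))
    stop_data("annotation table must have columns: ",
              paste(need, collapse = ", "))
  if (anyDuplicated(df[c("cell_id", "sample_id")]))
    stop_data("duplicate cell_id within a sample in ", path)
  df[need]
}

#' Read a pseudotime table
#'
#' Tab-separated with header; columns `cell_id`, `pseudotime` (finite,
#' non-negative). Pseudotime is consumed as an input (e.g. from a trajectory
#' inference tool run upstream).
#'
#' @param path file path.
#' @return data.frame with columns `cell_id`, `pseudotime`.
#' @export
read_pseudotime_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("cell_id", "pseudotime") %in% names(df)))
    stop_data("pseudotime table must have columns cell_id, pseudotime")
  if (anyDuplicated(df$cell_id)) stop_data("duplicate cell_id in ", path)
  pt <- df$pseudotime
  if (anyNA(pt) || any(!is.finite(pt)) || any(pt < 0))
    stop_data("pseudotime must be finite and >= 0")
  df[c("cell_id", "pseudotime")]
}

#' Read a one-symbol-per-line gene list
#' @param path file path (lines starting with `#` ignored).
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Cell-level quality-control configuration
#'
#' Cells are retained when the number of detected genes (count > 0) lies in
#' `[min_genes, max_genes]` and the mitochondrial fraction (mitochondrial
#' UMIs / total UMIs) is strictly below `max_mito_fraction`. Mitochondrial
#' genes are identified by symbol prefix (human convention `"MT-"`).
#' Defaults follow a 500-4000 detected-gene band with a 15% mitochondrial
#' ceiling, typical for bone-marrow 10x data.
#'
#' @param min_genes,max_genes inclusive detected-gene band.
#' @param max_mito_fraction mitochondrial fraction ceiling in `[0, 1]`
#'   (strict `<`).
#' @param mito_gene_prefix symbol prefix marking mitochondrial genes.
#' @return an object of class `"qc_config"`.
#' @export
qc_config <- function(min_genes = 500L, max_genes = 4000L,
                      max_mito_fraction = 0.15, mito_gene_prefix = "MT-") {
  if (min_genes > max_genes) stop_config("min_genes > max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop_config("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_config")
}

#' Apply cell-level QC filters
#'
#' Removes cells outside the detected-gene band or at/above the
#' mitochondrial-fraction ceiling (see [qc_config()]). Genes and retained
#' count values are untouched, so the operation is idempotent.
#'
#' @param x a `"count_matrix"`.
#' @param config a [qc_config()].
#' @return the filtered `"count_matrix"`, with an attribute `"qc_log"`
#'   (cells before/after and per-rule removal counts). Cell counts are also
#'   reported via `message()`.
#' @export
qc_filter_cells <- function(x, config = qc_config()) {
  x <- as_count_matrix(x)
  if (!inherits(config, "qc_config")) stop_config("config must be a qc_config")
  if (ncol(x$counts) == 0L) stop_data("matrix has no cells")
  detected <- Matrix::colSums(x$counts > 0)
  total <- Matrix::colSums(x$counts)
  sym <- if (is.null(x$gene_symbols)) x$gene_ids else x$gene_symbols
  mito_rows <- startsWith(sym, config$mito_gene_prefix)
  mito <- if (any(mito_rows))
    Matrix::colSums(x$counts[mito_rows, , drop = FALSE]) else numeric(ncol(x$counts))
  frac <- ifelse(total > 0, mito / total, 0)
  ok_genes <- detected >= config$min_genes & detected <= config$max_genes
  ok_mito <- frac < config$max_mito_fraction
  keep <- ok_genes & ok_mito
  if (!any(keep)) stop_data("QC removed every cell")
  out <- x[, keep]
  log <- list(cells_before = length(keep), cells_after = sum(keep),
              removed_gene_band = sum(!ok_genes),
              removed_mito = sum(ok_genes & !ok_mito))
  message(sprintf("QC: %d of %d cells retained (%d outside gene band, %d high mito)",
                  log$cells_after, log$cells_before,
                  log$removed_gene_band, log$removed_mito))
  attr(out, "qc_log") <- log
  out
}
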