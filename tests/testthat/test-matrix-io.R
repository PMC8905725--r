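make_cm <- function(m, genes = NULL, cells = NULL, symbols = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("C%03d", seq_len(ncol(m)))
  count_matrix(m, genes, cells, gene_symbols = symbols)
}

test_that("count matrix constructor enforces the invariants", {
  m <- matrix(c(0, 1, 2, 3, 0, 5), 2, 3)
  cm <- make_cm(m)
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm), c(2L, 3L))
  expect_error(count_matrix(m, c("A", "A"), c("c1", "c2", "c3")),
               "duplicate gene")
  expect_error(make_cm(matrix(c(1, -1), 1, 2)), "negative count")
  expect_error(make_cm(matrix(c(1, 1.5), 1, 2)), "non-integer")
  expect_warning(make_cm(m, symbols = c("ACTB", "ACTB")), "duplicate")
})

test_that("Matrix Market triplet round-trips exactly", {
  cm <- make_cm(matrix(c(0, 1, 2, 0, 0, 7), 2, 3),
                genes = c("ENSG01", "ENSG02"),
                symbols = c("MT-CO1", "GATA1"))
  dir <- withr::local_tempdir()
  write_matrix_market_triplet(cm, dir)
  back <- read_matrix_market_triplet(dir)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$gene_ids, cm$gene_ids)
  expect_equal(back$cell_ids, cm$cell_ids)
  expect_equal(back$gene_symbols, cm$gene_symbols)

  # header/barcode dimension mismatch is a hard error
  writeLines(readLines(file.path(dir, "barcodes.tsv"))[1:2],
             file.path(dir, "barcodes.tsv"))
  expect_error(read_matrix_market_triplet(dir), "barcodes.tsv has 2")
  expect_error(read_matrix_market_triplet(withr::local_tempdir()),
               "missing file")
})

test_that("a random sparse triplet matches an independent text parse", {
  set.seed(7)
  m <- matrix(0L, 50, 100)
  nz <- sample(length(m), round(0.1 * length(m)))
  m[nz] <- sample(1:20, length(nz), replace = TRUE)
  dir <- withr::local_tempdir()
  write_matrix_market_triplet(make_cm(m), dir)
  back <- read_matrix_market_triplet(dir)
  # brute-force parse of the coordinate lines
  lines <- readLines(file.path(dir, "matrix.mtx"))
  lines <- lines[!startsWith(lines, "%")][-1L]   # drop comments + size line
  trip <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  rebuilt <- matrix(0, 50, 100)
  rebuilt[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
  expect_equal(unname(as.matrix(back$counts)), rebuilt)
})

test_that("dense tables read in either orientation and reject bad counts", {
  m <- matrix(c(1, 0, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(m), f, sep = "\t", quote = FALSE,
                     col.names = NA)
  cm <- read_dense_table(f)
  expect_equal(unname(as.matrix(cm$counts)), unname(m))
  expect_equal(cm$gene_ids, rownames(m))

  # transposed file with the orientation flag flipped gives the same matrix
  ft <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(t(m)), ft, sep = "\t", quote = FALSE,
                     col.names = NA)
  cmt <- read_dense_table(ft, orientation = "cells_in_rows")
  expect_equal(as.matrix(cmt$counts), as.matrix(cm$counts))

  # negative entry is rejected naming the offender
  m2 <- m; m2["g2", "c1"] <- -1
  utils::write.table(as.data.frame(m2), f, sep = "\t", quote = FALSE,
                     col.names = NA)
  expect_error(read_dense_table(f), "gene 'g2', cell 'c1'")
})

test_that("dense writer round-trips through gzip", {
  cm <- make_cm(matrix(0:5, 2, 3))
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  write_dense_table(cm, f)
  expect_equal(as.matrix(read_dense_table(f)$counts), as.matrix(cm$counts))
})

test_that("QC filtering retains exactly the cells inside the gates", {
  # 200 cells x 30 genes (one mitochondrial); engineer 37 violations
  set.seed(3)
  n_genes <- 30L; n_cells <- 200L
  m <- matrix(rpois(n_genes * n_cells, 2) + 1L, n_genes, n_cells)
  m[5, ] <- 0L                         # baseline: 29 detected genes per cell
  genes <- c("MT-ND1", sprintf("G%03d", 2:n_genes))
  bad <- sample(n_cells, 37)
  low <- bad[1:15]; high_mito <- bad[16:30]; high_genes <- bad[31:37]
  m[5:n_genes, low] <- 0L              # 4 detected genes: below min
  m[1, high_mito] <- 500L              # mitochondrial fraction above cap
  m[5, high_genes] <- 1L               # all 30 genes detected: above max
  cfg <- qc_config(min_genes = 8L, max_genes = 29L, max_mito_fraction = 0.5,
                   mito_gene_prefix = "MT-")
  cm <- count_matrix(m, genes, sprintf("C%03d", 1:n_cells),
                     gene_symbols = genes)
  filt <- suppressMessages(qc_filter_cells(cm, cfg))
  # brute-force per-cell recount
  detected <- colSums(m > 0)
  frac <- m[1, ] / colSums(m)
  keep <- detected >= 8 & detected <= 29 & frac < 0.5
  expect_equal(sum(keep), 163L)
  expect_equal(filt$cell_ids, cm$cell_ids[keep])
  # retained values untouched, genes unchanged
  expect_equal(as.matrix(filt$counts), as.matrix(cm$counts[, keep]))
  expect_equal(filt$gene_ids, cm$gene_ids)
  # idempotent
  again <- suppressMessages(qc_filter_cells(filt, cfg))
  expect_equal(as.matrix(again$counts), as.matrix(filt$counts))
})

test_that("QC boundaries follow the documented conventions", {
  # cell 1: mito fraction exactly at the cap -> removed (strict <)
  # cell 2: detected genes exactly at min -> kept (inclusive band)
  m <- matrix(c(1, 1, 0,
                0, 2, 3), nrow = 3)
  cm <- count_matrix(m, c("MT-1", "GA", "GB"), c("c1", "c2"),
                     gene_symbols = c("MT-1", "GA", "GB"))
  cfg <- qc_config(min_genes = 2L, max_genes = 3L, max_mito_fraction = 0.5)
  filt <- suppressMessages(qc_filter_cells(cm, cfg))
  expect_equal(filt$cell_ids, "c2")
  expect_error(suppressMessages(
    qc_filter_cells(cm, qc_config(3L, 3L, 0.5))), "every cell")
})

test_that("annotation, pseudotime and gene-list readers validate input", {
  d <- withr::local_tempdir()
  ann <- data.frame(cell_id = c("a", "b"), population_label = c("HSC", "MEP"),
                    sample_id = "s1")
  fa <- file.path(d, "ann.tsv")
  utils::write.table(ann, fa, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_cell_annotation(fa), ann)

  pt <- data.frame(cell_id = c("a", "b"), pseudotime = c(0.1, 2))
  fp <- file.path(d, "pt.tsv")
  utils::write.table(pt, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_pseudotime_table(fp), pt)
  utils::write.table(transform(pt, pseudotime = c(-1, 2)), fp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_pseudotime_table(fp), "finite and >= 0")

  fg <- file.path(d, "tf.txt")
  writeLines(c("# TFs", "GATA1", "", "SPI1"), fg)
  expect_equal(read_gene_list(fg), c("GATA1", "SPI1"))
})
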