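#' @keywords internal
"_PACKAGE"

# Condition helpers: config errors (bad arguments / schemas) vs data errors
# (valid call, unusable data) get distinct classes so callers and the CLI can
# map them to distinct exit codes.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("icentropy_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("icentropy_data_error", "error")))
}

#' Write a table as TSV with a reproducibility header
#'
#' All tabular outputs of the workflow commands start with commented header
#' lines recording the package version and run metadata, so any result file
#' can be traced back to the exact configuration that produced it.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param meta named character vector of metadata to record in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(x, path, meta = character()) {
  meta <- c(package = "icentropy",
            version = as.character(utils::packageVersion("icentropy")),
            meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_header()]
#'
#' @param path file path.
#' @return data.frame; header metadata attached as attribute `"meta"`.
#' @export
read_tsv_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- character()
  if (length(hdr)) {
    kv <- sub("^# ", "", lines[hdr])
    meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  }
  x <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                         header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  attr(x, "meta") <- meta
  x
}

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever base the caller passes.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 9973) %% 2147483647L)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not clobber user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
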