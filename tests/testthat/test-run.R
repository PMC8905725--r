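write_config <- function(lines, dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
  f <- file.path(dir, "run.yaml")
  writeLines(lines, f)
  f
}

sim_config_lines <- function(out, n_cells = 200L, extra = character()) {
  c("seed: 5",
    paste0("out_dir: ", out),
    "simulate:",
    "  kind: trajectory",
    paste0("  n_cells: ", n_cells),
    "  n_switch_genes: 20",
    "  n_housekeeping_genes: 10",
    "  n_noise_genes: 60",
    extra)
}

test_that("run configs are validated before any compute", {
  f <- write_config(c("seed: 3", "out_dir: /tmp/x", "bogus_field: 1"))
  expect_error(read_run_config(f), "bogus_field")
  expect_error(read_run_config(file.path(tempdir(), "nope.yaml")),
               "no such config")
  f2 <- write_config(c("seed: 3", "out_dir: /tmp/x", "estimator: mean"))
  expect_error(read_run_config(f2), "estimator")
  f3 <- write_config(c("seed: 3", "out_dir: /tmp/x",
                       "window: {window_size: 50, stepp: 2}"))
  expect_error(read_run_config(f3), "stepp")
  # a valid config carries a stable hash
  f4 <- write_config(c("seed: 3", "out_dir: /tmp/x"))
  cfg <- read_run_config(f4)
  expect_s3_class(cfg, "run_config")
  expect_match(attr(cfg, "hash"), "^[0-9a-f]{32}$")
})

test_that("simulated datasets land on disk with a manifest and re-read", {
  out <- file.path(withr::local_tempdir(), "sim")
  f <- write_config(sim_config_lines(out))
  suppressMessages(run_simulate(f))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  back <- read_matrix_market_triplet(out)
  expect_equal(dim(back), c(90L, 200L))
  man <- yaml::read_yaml(file.path(out, "manifest.yaml"))
  expect_equal(man$seed, 5L)
  # same config twice: identical checksums
  out2 <- file.path(withr::local_tempdir(), "sim2")
  suppressMessages(run_simulate(write_config(sim_config_lines(out2))))
  man2 <- yaml::read_yaml(file.path(out2, "manifest.yaml"))
  expect_identical(unname(unlist(man$checksums)),
                   unname(unlist(man2$checksums)))
  # malformed kind fails schema validation
  bad <- write_config(c("seed: 1", "out_dir: /tmp/y", "simulate:",
                        "  kind: fancy"))
  expect_error(run_simulate(bad), "simulate.kind")
})

test_that("the profile and delta commands run end to end", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "data"); out <- file.path(root, "out")
  suppressMessages(run_simulate(
    write_config(sim_config_lines(data_dir), dir = root)))
  lines <- c("seed: 5",
             paste0("out_dir: ", out),
             "inputs:",
             paste0("  counts: ", data_dir),
             paste0("  annotation: ", file.path(data_dir, "annotation.tsv")),
             paste0("  pseudotime: ", file.path(data_dir, "pseudotime.tsv")),
             "window: {window_size: 50, step: 25}",
             "pathways:",
             "  - name: full",
             "    labels: [stage1, stage2, stage3, stage4, stage5]",
             "  - name: tiny",
             "    labels: [stage1]")
  f <- file.path(root, "profile.yaml")
  writeLines(lines, f)
  # the 40-cell stage1 pathway is skipped with a warning, the run succeeds
  expect_warning(peaks <- suppressMessages(run_entropy_profile(f)),
                 "tiny")
  expect_equal(peaks$pathway, "full")
  expect_equal(peaks$n_windows, (200 - 50) %/% 25 + 1)
  prof <- read_tsv_header(file.path(out, "full_profile.tsv"))
  expect_equal(nrow(prof), peaks$n_windows)
  expect_equal(attr(prof, "meta")[["seed"]], "5")

  # delta stage consumes the written matrices (single pathway: no overlap)
  lines2 <- lines[!grepl("tiny|stage1]$", lines)]
  f2 <- file.path(root, "delta.yaml")
  writeLines(lines2, f2)
  expect_warning(res <- suppressMessages(run_delta(f2)), "overlap")
  expect_true(file.exists(file.path(out, "full_delta.tsv")))
  expect_equal(nrow(res$deltas[[1]]), 90L)
  expect_length(res$top_entropy[[1]]$genes, 20L)
})

test_that("the compare command wires exclusions and writes both tables", {
  root <- withr::local_tempdir()
  out <- file.path(root, "cmp")
  suppressMessages(run_simulate(read_run_config(write_config(c(
    "seed: 4",
    paste0("out_dir: ", file.path(root, "tg")),
    "simulate:",
    "  kind: two_group",
    "  n_cells: 300",
    "  n_genes: 120"), dir = root))))
  writeLines(c("# sig", "G00001", "G00002", "G00003"),
             file.path(root, "sigA.txt"))
  writeLines(c("G00002", "G00003", "G00004"), file.path(root, "sigB.txt"))
  f <- write_config(c(
    "seed: 4",
    paste0("out_dir: ", out),
    "compare:",
    paste0("  sample_a: ", file.path(root, "tg", "control")),
    paste0("  sample_b: ", file.path(root, "tg", "case")),
    "  n_subsamples: 3",
    "  subsample_size: 100",
    paste0("  dissociation_a: ", file.path(root, "sigA.txt")),
    paste0("  dissociation_b: ", file.path(root, "sigB.txt"))), dir = root)
  res <- suppressMessages(run_compare(f))
  expect_equal(res$n_genes, 118L)      # two dissociation genes excluded
  tiers <- read_tsv_header(file.path(out, "comparison_tiers.tsv"))
  expect_equal(nrow(tiers), 4L)
  expect_equal(attr(tiers, "meta")[["n_excluded_genes"]], "2")
})

test_that("the command-line dispatcher maps error classes to exit codes", {
  cli <- system.file("cli", "icentropy.R", package = "icentropy")
  expect_true(nzchar(cli))
  root <- withr::local_tempdir()
  run_cli <- function(...) {
    # make sure the subprocess sees the same library paths as this session
    withr::with_envvar(
      c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
      suppressWarnings(system2("Rscript", c(cli, ...), stdout = FALSE,
                               stderr = FALSE)))
  }
  # valid simulate run exits 0
  ok <- write_config(sim_config_lines(file.path(root, "d"), n_cells = 60L),
                     dir = root)
  expect_equal(run_cli("simulate", "--config", ok), 0L)
  expect_true(file.exists(file.path(root, "d", "manifest.yaml")))
  # schema error exits 2
  bad <- file.path(root, "bad.yaml")
  writeLines(c("seed: 1", "out_dir: /tmp/z", "nonsense: true"), bad)
  expect_equal(run_cli("simulate", "--config", bad), 2L)
  # unknown command exits 1
  expect_equal(run_cli("frobnicate", "--config", ok), 1L)
})
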