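toy_dataset <- function() {
  m <- matrix(0:11, 3, 4,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3", "c4")))
  list(matrix = count_matrix(m),
       annotation = data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                               population_label = c("HSC", "MEP", "other",
                                                    "HSC"),
                               sample_id = "s"),
       pseudotime = data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                               pseudotime = c(0.9, 0.1, 0.5, 0.9)))
}

test_that("ordering filters to the pathway and sorts by pseudotime", {
  d <- toy_dataset()
  pw <- pathway_spec("toy", c("HSC", "MEP"))
  ord <- suppressMessages(build_ordering(d$matrix, d$annotation,
                                         d$pseudotime, pw))
  # c3 excluded (label not in pathway); tie at 0.9 broken lexicographically
  expect_equal(ord$cell_ids, c("c2", "c1", "c4"))
  expect_equal(ord$labels, c("MEP", "HSC", "HSC"))
  expect_true(!is.unsorted(ord$pseudotimes))

  expect_error(suppressMessages(build_ordering(
    d$matrix, d$annotation, d$pseudotime, pathway_spec("none", "NK"))),
    "no cells")
  pt2 <- d$pseudotime[-1L, ]
  expect_error(suppressMessages(build_ordering(
    d$matrix, d$annotation, pt2, pw)), "missing pseudotime")
})

test_that("ordering recovers the latent order of a simulated trajectory", {
  ds <- simulate_trajectory(small_traj_config(seed = 2))
  ord <- suppressMessages(build_ordering(
    ds$matrix, ds$annotation, ds$pseudotime,
    pathway_spec("sim", paste0("stage", 1:5))))
  latent <- match(ord$cell_ids, ds$pseudotime$cell_id)
  expect_equal(cor(seq_along(latent), latent, method = "spearman"), 1)
})

test_that("window start arithmetic emits exactly the full windows", {
  spec <- window_spec(50, 10)
  expect_equal(sliding_windows(50, spec), 1L)
  expect_length(sliding_windows(444, spec), 40L)
  expect_error(sliding_windows(49, spec, "erythro"), "erythro")
  # property sweep over random geometries
  set.seed(31)
  for (rep in 1:50) {
    ws <- sample(2:60, 1); st <- sample(ws, 1)
    n <- ws + sample(0:300, 1)
    starts <- sliding_windows(n, window_spec(ws, st))
    expect_length(starts, (n - ws) %/% st + 1)
    expect_true(all(starts + ws - 1 <= n))
    expect_true(all(diff(starts) == st))
  }
  expect_error(window_spec(1, 1), "window_size")
  expect_error(window_spec(10, 11), "step")
})

test_that("window profiles match a from-scratch recomputation", {
  set.seed(9)
  m <- matrix(rpois(3 * 60, c(0, 2, 8)), 3, 60,
              dimnames = list(c("zero", "lo", "hi"),
                              sprintf("c%02d", 1:60)))
  m["zero", ] <- 0L
  cm <- count_matrix(m)
  ann <- data.frame(cell_id = cm$cell_ids, population_label = "HSC",
                    sample_id = "s")
  pt <- data.frame(cell_id = cm$cell_ids,
                   pseudotime = seq(0, 1, length.out = 60))
  ord <- suppressMessages(build_ordering(cm, ann, pt,
                                         pathway_spec("p", "HSC")))
  for (est in c("bub", "plugin", "miller_madow", "jackknife")) {
    prof <- window_profiles(ord, cm, window_spec(50, 10), est,
                            cache = shared_cache)
    expect_equal(ncol(prof$entropy), 2L)
    for (w in 1:2) {
      idx <- prof$window_starts[w]:(prof$window_starts[w] + 49)
      cells <- ord$cell_ids[idx]
      for (g in rownames(m)) {
        expect_equal(unname(prof$entropy[g, w]),
                     estimate_entropy(m[g, cells], est, cache = shared_cache),
                     tolerance = 1e-12)
        expect_equal(unname(prof$mean_expr[g, w]), mean(m[g, cells]))
      }
    }
    expect_equal(prof$mean_entropy, colMeans(prof$entropy))
  }
  # all-zero gene contributes exactly zero everywhere
  prof <- window_profiles(ord, cm, window_spec(50, 10), cache = shared_cache)
  expect_true(all(prof$entropy["zero", ] == 0))
  expect_true(all(prof$mean_expr["zero", ] == 0))
})

test_that("profiles are invariant to shuffling cells within a window", {
  ds <- simulate_trajectory(small_traj_config(n_cells = 120L, seed = 4))
  ord <- suppressMessages(build_ordering(
    ds$matrix, ds$annotation, ds$pseudotime,
    pathway_spec("sim", paste0("stage", 1:5))))
  prof <- window_profiles(ord, ds$matrix, window_spec(60, 60),
                          cache = shared_cache)
  # permute the single window's cells and recompute
  set.seed(1)
  shuf <- ord
  perm <- c(sample(60), 61:120)
  shuf$cell_ids <- ord$cell_ids[perm]
  shuf$pseudotimes <- ord$pseudotimes[perm]
  shuf$labels <- ord$labels[perm]
  prof2 <- window_profiles(shuf, ds$matrix, window_spec(60, 60),
                           cache = shared_cache)
  expect_equal(prof2$entropy, prof$entropy)
  expect_equal(prof2$mean_expr, prof$mean_expr)
})

test_that("a constant gene has exactly zero plugin delta across windows", {
  m <- matrix(3L, 1, 80, dimnames = list("const", sprintf("c%02d", 1:80)))
  cm <- count_matrix(m)
  ann <- data.frame(cell_id = cm$cell_ids, population_label = "X",
                    sample_id = "s")
  pt <- data.frame(cell_id = cm$cell_ids, pseudotime = 1:80 / 80)
  ord <- suppressMessages(build_ordering(cm, ann, pt, pathway_spec("p", "X")))
  prof <- window_profiles(ord, cm, window_spec(50, 10), "plugin")
  expect_equal(max(prof$entropy) - min(prof$entropy), 0)
})

test_that("peak summary applies the declared tie-break and transience rule", {
  base <- list(first_cell_label = letters[1:5])
  mk <- function(me) structure(c(base, list(mean_entropy = me)),
                               class = "window_profiles")
  expect_equal(peak_summary(mk(c(5, 4, 3, 2, 1)))$argmax, 1L)
  expect_false(peak_summary(mk(c(5, 4, 3, 2, 1)))$is_transient)
  pk <- peak_summary(mk(c(1, 2, 5, 2, 1)))
  expect_equal(pk$argmax, 3L)
  expect_equal(pk$label, "c")
  expect_true(pk$is_transient)
  flat <- peak_summary(mk(rep(2, 5)))
  expect_equal(flat$argmax, 1L)
  expect_false(flat$is_transient)
  expect_error(peak_summary(mk(c(1, 2))), "3 windows")
})
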