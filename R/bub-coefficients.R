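#' Best Upper Bound (BUB) entropy estimator coefficients
#'
#' A linear entropy estimator \eqn{\hat H = \sum_j a_j h_j} has expectation
#' \eqn{\sum_{bins} \sum_j a_j B_{j,N}(p)} with \eqn{B_{j,N}} the Bernstein
#' basis \eqn{\binom{N}{j} p^j (1-p)^{N-j}}. The BUB coefficients make
#' \eqn{\sum_j a_j B_{j,N}(p)} approximate the entropy integrand
#' \eqn{-p \log p} uniformly on \eqn{[0,1]} while keeping the coefficient
#' increments small, which bounds the worst-case bias
#' (\eqn{m \cdot \max_p |\mathrm{residual}|}) and, by bounded differences,
#' the variance (\eqn{N (\max_j |a_{j+1}-a_j|)^2}). This is the estimator of
#' choice in the undersampled regime \eqn{N/m < 100} typical of sliding
#' windows of 50 cells.
#'
#' Construction: coefficients with \eqn{j \le k_{max}} are free and fitted
#' by penalised least squares on a uniform mesh over \eqn{p}, minimising
#' \deqn{m^2 \sum_k \big(\textstyle\sum_j a_j B_{j,N}(p_k) + p_k \log
#' p_k\big)^2 + \lambda \sum_j (a_{j+1} - a_j)^2,}
#' i.e. residuals are weighted by the bin count so that the fit term and the
#' smoothness penalty live on the scale of the squared bias and variance
#' bounds respectively (which is why the solution depends on \eqn{m}, not
#' only on \eqn{N}). Coefficients with \eqn{j > k_{max}} are anchored to the
#' bias-corrected plugin form \eqn{-(j/N)\log(j/N) + 1/(2N)}, where the
#' plugin estimator is already nearly unbiased. The returned vector is the
#' grid candidate minimising the combined bound
#' \eqn{\sqrt{(m \max|res|)^2 + N (\max|\Delta a|)^2}}.
#'
#' @param N number of cells (samples) per histogram.
#' @param m number of bins (possible expression levels).
#' @param k_max_grid integer vector of candidate cut-offs for the free
#'   coefficient block. Defaults to `c(10, 20, 30, min(N, 60))` (clipped to
#'   `N`).
#' @param lambda_grid non-negative smoothness penalty weights; defaults to
#'   `c(0, N/4, N, 4*N)`.
#' @param mesh_size number of uniform mesh points on `[0, 1]` for the
#'   least-squares fit (default 2000).
#' @return an object of class `"bub_coefficients"`: list with `N`, `m`,
#'   `a` (length `N + 1`), `k_max`, `lambda`, `error_bound`, `max_resid`,
#'   `max_dabs`.
#' @references Paninski (2003), Neural Computation 15:1191-1253.
#' @export
bub_coefficients <- function(N, m, k_max_grid = NULL, lambda_grid = NULL,
                             mesh_size = 2000L) {
  N <- as.integer(N); m <- as.integer(m)
  if (N < 1L || m < 1L) stop_config("N and m must be >= 1")
  bub_solve(bub_prep(N, k_max_grid = k_max_grid, lambda_grid = lambda_grid,
                     mesh_size = mesh_size), m)
}

#' @export
print.bub_coefficients <- function(x, ...) {
  cat(sprintf(paste0("BUB coefficients: N = %d, m = %d, k_max = %d, ",
                     "lambda = %.4g\n  error bound %.4g ",
                     "(bias %.4g, sd %.4g) nats\n"),
              x$N, x$m, x$k_max, x$lambda, x$error_bound,
              x$m * x$max_resid, sqrt(x$N) * x$max_dabs))
  invisible(x)
}

# Per-N preparation shared by every m: the Bernstein design restricted to
# the largest free block, the anchored-tail contribution on the mesh, the
# target, and the per-k_max normal-equation pieces. Evaluated in log space
# (lchoose + j log p) so it stays stable at N = 700 and beyond; the full
# mesh x (N + 1) basis is only ever built chunk-wise.
bub_prep <- function(N, k_max_grid = NULL, lambda_grid = NULL,
                     mesh_size = 2000L) {
  N <- as.integer(N)
  mesh_size <- as.integer(mesh_size)
  if (mesh_size < 2L) stop_config("mesh_size must be >= 2")
  if (is.null(k_max_grid)) k_max_grid <- c(10L, 20L, 30L, min(N, 60L))
  k_max_grid <- sort(unique(pmin(as.integer(k_max_grid), N)))
  if (!length(k_max_grid)) stop_config("k_max_grid is empty")
  if (is.null(lambda_grid)) lambda_grid <- c(0, N / 4, N, 4 * N)
  lambda_grid <- sort(unique(as.double(lambda_grid)))
  if (!length(lambda_grid) || any(lambda_grid < 0))
    stop_config("lambda_grid must be non-empty and non-negative")

  p <- seq(0, 1, length.out = mesh_size)
  f <- -p * log(p)
  f[p == 0] <- 0                       # continuous extension of -p log p

  j_all <- 0:N
  # Anchor vector: bias-corrected plugin coefficients.
  aplug <- -(j_all / N) * log(j_all / N) + 1 / (2 * N)
  aplug[1L] <- 1 / (2 * N)             # j = 0 term of -(j/N)log(j/N) is 0

  Kbig <- max(k_max_grid)
  B_small <- matrix(0, mesh_size, Kbig + 1L)
  g <- numeric(mesh_size)              # sum_j B_j(p) aplug_j over ALL j
  lch <- lchoose(N, j_all)
  chunk <- max(1L, as.integer(2e6 %/% (N + 1L)))
  for (lo in seq(1L, mesh_size, by = chunk)) {
    hi <- min(lo + chunk - 1L, mesh_size)
    pc <- p[lo:hi]
    lp <- log(pc); lq <- log1p(-pc)
    LB <- matrix(lch, hi - lo + 1L, N + 1L, byrow = TRUE) +
      outer(lp, j_all) + outer(lq, N - j_all)
    Bc <- exp(LB)
    if (any(pc == 0)) { Bc[pc == 0, ] <- 0; Bc[pc == 0, 1L] <- 1 }
    if (any(pc == 1)) { Bc[pc == 1, ] <- 0; Bc[pc == 1, N + 1L] <- 1 }
    B_small[lo:hi, ] <- Bc[, seq_len(Kbig + 1L), drop = FALSE]
    g[lo:hi] <- Bc %*% aplug
  }

  blocks <- lapply(k_max_grid, function(k_max) {
    nf <- k_max + 1L                   # free coefficients a_0 .. a_k_max
    Bf <- B_small[, seq_len(nf), drop = FALSE]
    anch <- as.numeric(g - Bf %*% aplug[seq_len(nf)])
    r <- f - anch
    # First-difference penalty rows within the free block, plus the boundary
    # difference against the first anchored coefficient (when one exists).
    nd <- (nf - 1L) + as.integer(k_max < N)
    D <- matrix(0, nd, nf); t0 <- numeric(nd)
    if (nf > 1L) for (i in seq_len(nf - 1L)) { D[i, i] <- -1; D[i, i + 1L] <- 1 }
    if (k_max < N) { D[nd, nf] <- -1; t0[nd] <- -aplug[nf + 1L] }
    BtB <- crossprod(Bf)
    list(k_max = k_max, nf = nf, Bf = Bf, anch = anch,
         BtB = BtB, Btr = crossprod(Bf, r),
         DtD = crossprod(D), Dtt = crossprod(D, t0),
         jitter = 1e-10 * mean(diag(BtB)) * diag(nf))
  })
  list(N = N, f = f, aplug = aplug, lambda_grid = lambda_grid,
       blocks = blocks)
}

# Solve the penalised fit for one bin count m over the (k_max, lambda) grid
# and return the bound-minimising candidate. Dividing the normal equations
# by m^2 turns the m^2-weighted objective into an effective penalty
# lambda / m^2 on the unweighted system.
bub_solve <- function(prep, m) {
  m <- as.integer(m)
  N <- prep$N
  best <- NULL
  for (blk in prep$blocks) {
    for (lambda in prep$lambda_grid) {
      le <- lambda / as.double(m)^2
      x <- solve(blk$BtB + le * blk$DtD + blk$jitter,
                 blk$Btr + le * blk$Dtt)
      a <- prep$aplug
      a[seq_len(blk$nf)] <- x
      res <- blk$Bf %*% x + blk$anch - prep$f
      max_resid <- max(abs(res))
      max_dabs <- max(abs(diff(a)))
      eb <- sqrt((m * max_resid)^2 + N * max_dabs^2)
      if (is.null(best) || eb < best$error_bound) {
        best <- list(N = N, m = m, a = as.numeric(a), k_max = blk$k_max,
                     lambda = lambda, error_bound = eb,
                     max_resid = max_resid, max_dabs = max_dabs)
      }
    }
  }
  structure(best, class = "bub_coefficients")
}

#' Memoising cache for BUB coefficients
#'
#' Along a trajectory the window size \eqn{N} is fixed while the bin count
#' \eqn{m} changes with every gene and window, so the work is memoised at
#' two levels: the Bernstein design and normal-equation blocks are built
#' once per \eqn{N}, and the per-\eqn{m} penalised solves and bound
#' minimisation once per \eqn{(N, m)} pair. Queries are deterministic:
#' repeated calls return identical vectors.
#'
#' @param k_max_grid,lambda_grid,mesh_size passed through to
#'   [bub_coefficients()]; fixed at cache creation so all cached entries
#'   share one solver configuration.
#' @return an object of class `"bub_cache"`.
#' @seealso [cache_get()], [write_bub_cache()]
#' @export
bub_cache <- function(k_max_grid = NULL, lambda_grid = NULL,
                      mesh_size = 2000L) {
  structure(list(coeffs = new.env(parent = emptyenv()),
                 preps = new.env(parent = emptyenv()),
                 counter = new.env(parent = emptyenv()),
                 k_max_grid = k_max_grid, lambda_grid = lambda_grid,
                 mesh_size = mesh_size),
            class = "bub_cache")
}

#' Fetch (or solve and memoise) BUB coefficients for one (N, m)
#'
#' @param cache a [bub_cache()].
#' @param N,m histogram dimensions.
#' @return a `"bub_coefficients"` object.
#' @export
cache_get <- function(cache, N, m) {
  key <- paste0(N, ":", m)
  hit <- get0(key, envir = cache$coeffs, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  nk <- as.character(N)
  prep <- get0(nk, envir = cache$preps, inherits = FALSE)
  if (is.null(prep)) {
    prep <- bub_prep(as.integer(N), k_max_grid = cache$k_max_grid,
                     lambda_grid = cache$lambda_grid,
                     mesh_size = cache$mesh_size)
    assign(nk, prep, envir = cache$preps)
  }
  val <- bub_solve(prep, m)
  assign(key, val, envir = cache$coeffs)
  assign("solves", cache_solves(cache) + 1L, envir = cache$counter)
  val
}

#' Number of distinct (N, m) solves a cache has performed
#' @param cache a [bub_cache()].
#' @return integer count.
#' @export
cache_solves <- function(cache) {
  get0("solves", envir = cache$counter, ifnotfound = 0L)
}

#' Persist cached BUB coefficients as TSV
#'
#' One row per cached \eqn{(N, m)} entry with columns `N`, `m`, `k_max`,
#' `lambda`, `error_bound` and the coefficients `a_0 .. a_N` (rows for
#' smaller `N` padded with NA), for reproducibility audits.
#'
#' @param cache a [bub_cache()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bub_cache <- function(cache, path) {
  keys <- ls(cache$coeffs)
  if (!length(keys)) stop_data("cache is empty")
  entries <- lapply(keys, get, envir = cache$coeffs)
  nmax <- max(vapply(entries, function(e) e$N, integer(1)))
  rows <- lapply(entries, function(e) {
    a <- c(e$a, rep(NA_real_, nmax - e$N))
    c(N = e$N, m = e$m, k_max = e$k_max, lambda = e$lambda,
      error_bound = e$error_bound, stats::setNames(a, paste0("a_", 0:nmax)))
  })
  df <- as.data.frame(do.call(rbind, rows))
  df <- df[order(df$N, df$m), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
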