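# Independent oracles used to cross-check the package's own routines.
# These are deliberately written as direct, slow, per-sample scans and grid
# searches so that they share no code path with the implementation.

# Brute-force local maxima + topographic prominence, per-sample scans.
# A local maximum is strictly higher than the nearest differing neighbour on
# each side; plateau tops report their first sample. Prominence:
# height - max(lowest value to the nearest strictly higher sample on the
# left, same on the right), trace ends counting as boundaries.
bf_peak_prominences <- function(y) {
  n <- length(y)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j <= n - 1L && y[j + 1L] == y[i]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[i]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  prom <- vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    higher <- which(left > h)
    lmin <- min(left[seq.int(from = if (length(higher)) max(higher) + 1L else 1L,
                             to = p - 1L)])
    right <- y[(p + 1L):n]
    higher <- which(right > h)
    rmin <- min(right[seq.int(from = 1L,
                              to = if (length(higher)) min(higher) - 1L else n - p)])
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, height = y[idx], prominence = prom)
}

# Brute-force detector: prominence filter + greedy separation thinning
# (highest first, ties to the earlier sample), mirroring the documented
# selection rule but through the brute-force prominence scan above.
bf_detect_peaks <- function(y, min_prominence, min_sep_samples) {
  pk <- bf_peak_prominences(y)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (!nrow(pk)) return(integer(0))
  ord <- order(-pk$height, pk$index)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) ||
        all(abs(pk$index[kept] - pk$index[j]) >= min_sep_samples)) {
      kept <- c(kept, j)
    }
  }
  sort(pk$index[kept])
}

# Grid-search + golden-section oracle for the single-exponential decay fit.
# For fixed k the model A*exp(-k*t) + C is linear in (A, C), so SSE(k) is
# profiled by linear least squares and minimized over a dense log-grid,
# then refined by golden-section search.
grid_fit_decay <- function(time, value, k_range = c(1e-2, 1e2),
                           n_grid = 600, tol = 1e-8) {
  tt <- time - time[1]
  sse <- function(k) {
    x <- exp(-k * tt)
    fit <- stats::lm.fit(cbind(x, 1), value)
    sum(fit$residuals^2)
  }
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
  vals <- vapply(ks, sse, numeric(1))
  i <- which.min(vals)
  lo <- ks[max(1L, i - 1L)]
  hi <- ks[min(n_grid, i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- sse(c1); f2 <- sse(c2)
  while (b - a > tol * b) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- sse(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- sse(c2)
    }
  }
  k <- (a + b) / 2
  x <- exp(-k * tt)
  cf <- stats::lm.fit(cbind(x, 1), value)$coefficients
  list(k = k, A = unname(cf[1]), C = unname(cf[2]))
}
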