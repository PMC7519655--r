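# Independent oracles, deliberately written along different lines than the
# package implementations they check.

# Exhaustive neighbour scan (plain loop over all electrodes).
oracle_neighbors <- function(array, center, radius) {
  p <- electrode_positions(array, center)
  out <- integer(0)
  for (i in seq_along(array$ids)) {
    if (array$ids[i] == center) next
    d <- sqrt((array$x[i] - p[1, 1])^2 + (array$y[i] - p[1, 2])^2)
    if (d <= radius + 1e-6) out <- c(out, array$ids[i])
  }
  sort(out)
}

# Exhaustive CCG by full pair enumeration (outer difference + cut).
oracle_ccg_counts <- function(a, b, bin_ms = 1, window_ms = 50) {
  nb <- window_ms / bin_ms
  edges <- (seq(-nb, nb + 1) - 0.5) * bin_ms
  dt <- as.vector(outer(b, a, "-")) * 1000
  dt <- dt[dt >= edges[1] & dt < edges[length(edges)]]
  as.vector(table(cut(dt, edges)))
}

# Smallest k with Poisson CDF(k; lambda) >= 1 - alpha, by direct search.
oracle_poisson_band <- function(lambda, alpha) {
  vapply(lambda, function(l) {
    k <- 0
    while (ppois(k, l) < 1 - alpha) k <- k + 1
    k
  }, numeric(1))
}

# Full independent implementation of the connection test used for the
# Monte-Carlo calibration check: two-pointer CCG, loop convolution null
# with a hollow Gaussian, Poisson band by direct search.
oracle_connection_detected <- function(a, b, bin_ms = 1, window_ms = 50,
                                       peak_window_ms = 5, alpha = 0.01,
                                       null_sigma_ms = 10, hollow = 0.6) {
  w <- (window_ms + bin_ms / 2) / 1000
  dts <- vector("list", length(a))
  j0 <- 1L
  nb_len <- length(b)
  for (i in seq_along(a)) {
    while (j0 <= nb_len && b[j0] < a[i] - w) j0 <- j0 + 1L
    j <- j0
    if (j > nb_len) break
    jhi <- j
    while (jhi <= nb_len && b[jhi] <= a[i] + w) jhi <- jhi + 1L
    if (jhi > j) dts[[i]] <- b[j:(jhi - 1L)] - a[i]
  }
  dt_ms <- unlist(dts) * 1000
  nb <- window_ms / bin_ms
  edges <- (seq(-nb, nb + 1) - 0.5) * bin_ms
  counts <- as.vector(table(cut(dt_ms, edges)))
  lags <- seq(-nb, nb) * bin_ms
  m <- ceiling(3 * null_sigma_ms / bin_ms)
  kern <- dnorm(seq(-m, m) * bin_ms, 0, null_sigma_ms)
  kern[m + 1] <- kern[m + 1] * (1 - hollow)
  n <- length(counts)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0; wsum <- 0
    for (o in seq(-m, m)) {
      j <- i + o
      if (j >= 1 && j <= n) {
        s <- s + counts[j] * kern[o + m + 1]
        wsum <- wsum + kern[o + m + 1]
      }
    }
    pred[i] <- s / wsum
  }
  band <- oracle_poisson_band(pred, alpha)
  any(counts > band & abs(lags) <= peak_window_ms & lags != 0)
}
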