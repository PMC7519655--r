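#' Burst-detection parameters
#'
#' @param bin_s spike-count bin, seconds (default 0.01).
#' @param kernel_sigma_s Gaussian smoothing kernel sd, seconds (default 0.3).
#' @param threshold_factor burst threshold as a multiple of the baseline
#'   rate (default 1.35).
#' @param baseline `"median"` (robust to bursts, default) or `"mean"`.
#' @export
burst_params <- function(bin_s = 0.01, kernel_sigma_s = 0.3,
                         threshold_factor = 1.35,
                         baseline = c("median", "mean")) {
  if (bin_s <= 0 || kernel_sigma_s <= 0 || threshold_factor <= 0)
    stop("invalid parameter: burst parameters must be > 0")
  structure(list(bin_s = bin_s, kernel_sigma_s = kernel_sigma_s,
                 threshold_factor = threshold_factor,
                 baseline = match.arg(baseline)),
            class = "burst_params")
}

#' Smoothed population firing rate
#'
#' Spikes of all units are counted in `bin_s` bins, converted to Hz, and
#' smoothed with a normalized Gaussian kernel of sd `kernel_sigma_s`
#' (truncated at 4 sd, zero-padded convolution), so the integral of the
#' rate equals the total spike count up to edge effects.
#'
#' @param trains list of spike-time vectors, seconds.
#' @param duration_s analysis span, seconds.
#' @param params [burst_params()].
#' @return object of class `population_rate`: list `t` (bin centres, s),
#'   `rate_hz`, `bin_s`, `n_spikes`.
#' @export
population_rate <- function(trains, duration_s, params = burst_params()) {
  bin <- params$bin_s
  n_bins <- ceiling(duration_s / bin)
  all_t <- unlist(trains, use.names = FALSE)
  all_t <- all_t[all_t >= 0 & all_t < duration_s]
  counts <- if (length(all_t))
    tabulate(pmin(floor(all_t / bin) + 1L, n_bins), nbins = n_bins)
  else numeric(n_bins)
  rate <- counts / bin
  m <- ceiling(4 * params$kernel_sigma_s / bin)
  k <- stats::dnorm(seq(-m, m) * bin, 0, params$kernel_sigma_s)
  k <- k / sum(k)
  padded <- c(numeric(m), rate, numeric(m))
  sm <- stats::filter(padded, k, method = "convolution", sides = 2L)
  sm <- as.numeric(sm[(m + 1L):(m + n_bins)])
  structure(list(t = (seq_len(n_bins) - 0.5) * bin, rate_hz = sm,
                 bin_s = bin, n_spikes = length(all_t)),
            class = "population_rate")
}

#' Detect network bursts on a population rate
#'
#' Bursts are contiguous intervals where the smoothed population rate
#' exceeds `threshold_factor` times the baseline rate (median of the
#' smoothed rate by default). Duration is threshold-crossing to
#' threshold-crossing; one rate peak is reported per burst; the interburst
#' interval (IBI) runs from a burst's offset to the next burst's onset
#' (onset-to-onset available via `ibi = "onset"`).
#'
#' @param pr a [population_rate()].
#' @param params [burst_params()].
#' @param ibi `"offset"` (offset-to-next-onset, default) or `"onset"`.
#' @return list with `bursts` (data.frame `onset_s, peak_s, offset_s,
#'   duration_s, peak_rate_hz`), `ibis_s`, `baseline_hz`, `threshold_hz`.
#' @export
detect_bursts <- function(pr, params = burst_params(),
                          ibi = c("offset", "onset")) {
  ibi <- match.arg(ibi)
  base_fun <- if (params$baseline == "median") stats::median else mean
  baseline <- base_fun(pr$rate_hz)
  thr <- params$threshold_factor * baseline
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      peak_rate_hz = numeric(0))
  if (!any(pr$rate_hz > thr) || all(pr$rate_hz == 0))
    return(list(bursts = empty, ibis_s = numeric(0),
                baseline_hz = baseline, threshold_hz = thr))
  above <- pr$rate_hz > thr
  d <- diff(c(FALSE, above, FALSE))
  on_i <- which(d == 1L)
  off_i <- which(d == -1L) - 1L
  bursts <- data.frame(
    onset_s = pr$t[on_i] - pr$bin_s / 2,
    peak_s = mapply(function(a, b) pr$t[a - 1L + which.max(pr$rate_hz[a:b])],
                    on_i, off_i),
    offset_s = pr$t[off_i] + pr$bin_s / 2)
  bursts$duration_s <- bursts$offset_s - bursts$onset_s
  bursts$peak_rate_hz <- mapply(function(a, b) max(pr$rate_hz[a:b]), on_i, off_i)
  n <- nrow(bursts)
  ibis <- if (n < 2L) numeric(0)
  else if (ibi == "offset") bursts$onset_s[-1L] - bursts$offset_s[-n]
  else diff(bursts$onset_s)
  list(bursts = bursts, ibis_s = ibis, baseline_hz = baseline,
       threshold_hz = thr)
}

#' Cross-correlogram parameters
#'
#' @param bin_ms CCG bin width, ms (default 1).
#' @param window_ms half-width of the lag window, ms (default 50).
#' @param peak_window_ms half-width of the connection-peak window, ms
#'   (default 5).
#' @param alpha significance level of the Poisson band (default 0.01).
#' @param null_sigma_ms sd of the convolution-null Gaussian kernel, ms
#'   (default 10).
#' @param hollow_frac fraction of the kernel's centre-bin weight removed
#'   ("partially hollow" kernel; default 0.6).
#' @param min_spikes pairs with fewer spikes in either train are not
#'   tested (default 50).
#' @export
ccg_params <- function(bin_ms = 1, window_ms = 50, peak_window_ms = 5,
                       alpha = 0.01, null_sigma_ms = 10, hollow_frac = 0.6,
                       min_spikes = 50L) {
  if (peak_window_ms > window_ms)
    stop("invalid parameter: peak_window_ms must be <= window_ms")
  if (alpha <= 0 || alpha >= 1) stop("invalid parameter: alpha in (0, 1)")
  structure(list(bin_ms = bin_ms, window_ms = window_ms,
                 peak_window_ms = peak_window_ms, alpha = alpha,
                 null_sigma_ms = null_sigma_ms, hollow_frac = hollow_frac,
                 min_spikes = as.integer(min_spikes)),
            class = "ccg_params")
}

#' Cross-correlogram of two spike trains
#'
#' `counts[l]` is the number of spike pairs with `t_b - t_a` falling in the
#' lag bin centred on `l * bin_ms`; the lag-0 bin is centred on zero. By
#' construction `ccg(a, b)` at lag `+l` equals `ccg(b, a)` at `-l`.
#'
#' @param a,b sorted spike-time vectors, seconds.
#' @param params [ccg_params()].
#' @return object of class `ccg`: list `lag_ms`, `counts`, `n_a`, `n_b`,
#'   `params`.
#' @export
compute_ccg <- function(a, b, params = ccg_params()) {
  nb <- as.integer(round(params$window_ms / params$bin_ms))
  counts <- integer(2L * nb + 1L)
  if (length(a) && length(b)) {
    if (is.unsorted(a) || is.unsorted(b)) stop("spike trains must be sorted")
    w <- (params$window_ms + params$bin_ms / 2) / 1000
    lo <- findInterval(a - w, b)
    hi <- findInterval(a + w, b)
    n_each <- hi - lo
    has <- n_each > 0L
    if (any(has)) {
      jb <- sequence(n_each[has]) + rep(lo[has], n_each[has])
      dt_ms <- (b[jb] - rep(a[has], n_each[has])) * 1000
      k <- as.integer(round(dt_ms / params$bin_ms))
      k <- k[abs(k) <= nb]
      counts <- tabulate(k + nb + 1L, nbins = 2L * nb + 1L)
    }
  }
  structure(list(lag_ms = (-nb:nb) * params$bin_ms, counts = counts,
                 n_a = length(a), n_b = length(b), params = params),
            class = "ccg")
}

#' Convolution-null predictor and significance band for a CCG
#'
#' The slow co-modulation baseline of a CCG is estimated by convolving the
#' observed counts with a partially hollow Gaussian kernel (the centre-bin
#' weight reduced by `hollow_frac` and the kernel renormalized, so a sharp
#' peak does not predict itself; edges renormalized over the available
#' bins). The pointwise upper significance band is the Poisson
#' `1 - alpha` quantile at the predicted mean.
#'
#' @param ccg a [compute_ccg()] result.
#' @param params [ccg_params()].
#' @return list `predictor`, `upper`, `significant` (counts strictly above
#'   the band), `alpha`.
#' @export
convolution_null <- function(ccg, params = ccg_params()) {
  n <- length(ccg$counts)
  m <- ceiling(3 * params$null_sigma_ms / params$bin_ms)
  if (2L * m + 1L > n)
    stop("invalid parameter: null kernel wider than the CCG window")
  k <- stats::dnorm(seq(-m, m) * params$bin_ms, 0, params$null_sigma_ms)
  k[m + 1L] <- k[m + 1L] * (1 - params$hollow_frac)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - m):(i + m)
    ok <- j >= 1L & j <= n
    w <- k[ok]
    pred[i] <- sum(ccg$counts[j[ok]] * w) / sum(w)
  }
  upper <- stats::qpois(1 - params$alpha, pred)
  list(predictor = pred, upper = upper,
       significant = ccg$counts > upper, alpha = params$alpha)
}

#' Detect a putative monosynaptic connection from a CCG
#'
#' A connection is called when a CCG bin within `+/- peak_window_ms`
#' (excluding lag 0, which carries no direction) strictly exceeds the
#' convolution-null band. The connection lag is the significant bin with
#' the largest excess over the predictor (ties toward the smaller |lag|);
#' a positive lag means the reference train `a` drives `b`, a negative lag
#' the reverse. A band-exceeding lag-0 bin alone is flagged as ambiguous
#' (likely common input) and yields no connection.
#'
#' @param ccg a [compute_ccg()] result.
#' @param null a [convolution_null()] result.
#' @param params [ccg_params()].
#' @return `NULL` if no connection; a list `ambiguous = TRUE` when only
#'   lag 0 was significant; otherwise a list `pre` (`"a"` or `"b"`),
#'   `post`, `lag_ms`, `latency_ms`, `excess` (counts above the predictor
#'   at the peak).
#' @export
detect_connection <- function(ccg, null, params = ccg_params()) {
  inwin <- abs(ccg$lag_ms) <= params$peak_window_ms
  sig <- which(null$significant & inwin & ccg$lag_ms != 0)
  if (!length(sig)) {
    if (any(null$significant & inwin & ccg$lag_ms == 0))
      return(list(ambiguous = TRUE))
    return(NULL)
  }
  excess <- ccg$counts[sig] - null$predictor[sig]
  o <- order(-excess, abs(ccg$lag_ms[sig]), ccg$lag_ms[sig])
  best <- sig[o[1L]]
  lag <- ccg$lag_ms[best]
  list(pre = if (lag > 0) "a" else "b",
       post = if (lag > 0) "b" else "a",
       lag_ms = lag, latency_ms = abs(lag),
       excess = ccg$counts[best] - null$predictor[best])
}

#' All-to-all connectivity graph
#'
#' Runs the CCG + convolution-null test on every unit pair (both
#' directions are read off the single CCG's peak sign), skipping pairs
#' with fewer than `min_spikes` spikes in either train. Each unit's
#' centre is its footprint amplitude-maximum electrode position; edge
#' distance is the Euclidean centre-to-centre distance.
#'
#' @param trains named list of sorted spike-time vectors.
#' @param centers data.frame `unit, x, y` (um), one row per unit.
#' @param params [ccg_params()].
#' @return object of class `mea_network`: list `edges` (data.frame
#'   `pre, post, latency_ms, distance_um, excess`), `degrees` (data.frame
#'   `unit, degree, in_degree, out_degree`), `graph` (igraph), `untested`
#'   (pair count skipped for insufficient spikes).
#' @export
build_graph <- function(trains, centers, params = ccg_params()) {
  units <- names(trains)
  stopifnot(!is.null(units), all(units %in% as.character(centers$unit)))
  n <- length(units)
  edges <- list()
  untested <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(trains[[i]]) < params$min_spikes ||
        length(trains[[j]]) < params$min_spikes) {
      untested <- untested + 1L
      next
    }
    cc <- compute_ccg(trains[[i]], trains[[j]], params)
    conn <- detect_connection(cc, convolution_null(cc, params), params)
    if (is.null(conn) || is.null(conn$pre)) next
    pre <- if (conn$pre == "a") units[i] else units[j]
    post <- if (conn$pre == "a") units[j] else units[i]
    ci <- centers[match(pre, as.character(centers$unit)), ]
    cj <- centers[match(post, as.character(centers$unit)), ]
    edges[[length(edges) + 1L]] <- data.frame(
      pre = pre, post = post, latency_ms = conn$latency_ms,
      distance_um = sqrt((ci$x - cj$x)^2 + (ci$y - cj$y)^2),
      excess = conn$excess)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(pre = character(0), post = character(0),
                  latency_ms = numeric(0), distance_um = numeric(0),
                  excess = numeric(0))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = units))
  degrees <- data.frame(
    unit = units,
    degree = as.integer(igraph::degree(g, mode = "all")),
    in_degree = as.integer(igraph::degree(g, mode = "in")),
    out_degree = as.integer(igraph::degree(g, mode = "out")))
  structure(list(edges = edges, degrees = degrees, graph = g,
                 untested = untested),
            class = "mea_network")
}

#' @export
print.mea_network <- function(x, ...) {
  cat(sprintf("<mea_network> %d units, %d putative connections (%d pairs untested)\n",
              nrow(x$degrees), nrow(x$edges), x$untested))
  invisible(x)
}
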