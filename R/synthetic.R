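#' Biphasic extracellular spike template
#'
#' Unit-amplitude stereotype of an extracellular action potential: a
#' negative lobe (sodium influx) followed by a smaller positive lobe,
#' 1 ms total by default, with the negative peak (value -1) at 30% of the
#' duration. Returned as a vectorized function of time in seconds since
#' event onset; zero outside `[0, duration]`.
#'
#' @param duration_ms total template duration.
#' @param neg_frac fraction of the duration taken by the negative lobe.
#' @param pos_amp amplitude of the positive lobe relative to the negative.
#' @return function `w(t_s)`; attributes `duration_s` and `peak_s` (time of
#'   the negative peak).
#' @export
biphasic_template <- function(duration_ms = 1, neg_frac = 0.6, pos_amp = 0.35) {
  dur <- duration_ms / 1000
  t_neg <- dur * neg_frac
  f <- function(t) {
    w <- numeric(length(t))
    i <- t >= 0 & t <= t_neg
    w[i] <- -sin(pi * t[i] / t_neg)
    j <- t > t_neg & t <= dur
    w[j] <- pos_amp * sin(pi * (t[j] - t_neg) / (dur - t_neg))
    w
  }
  attr(f, "duration_s") <- dur
  attr(f, "peak_s") <- t_neg / 2
  f
}

#' Spatial amplitude decay of extracellular signals
#'
#' Amplitude seen by an electrode at lateral distance `d_um` from a signal
#' source: `1 / (1 + d/lambda)`. With the default `lambda = 10` um an axonal
#' source of ~30 uV appears at 5-10 uV one electrode pitch (18 um) away,
#' the range reported for axonal signals on this class of array.
#'
#' @param d_um distance in um.
#' @param lambda_um decay constant in um.
#' @export
spatial_decay <- function(d_um, lambda_um = 10) 1 / (1 + d_um / lambda_um)

#' Broadband standard deviation matching an in-band noise figure
#'
#' Mode noise is specified as rms in the action-potential band (0.3-5 kHz).
#' White Gaussian samples at rate `fs` spread their power uniformly up to
#' Nyquist, so the generator scales the broadband sd such that the rms
#' within the AP band equals `noise_rms`.
#'
#' @param noise_rms target in-band rms, uV.
#' @param fs sampling rate, Hz.
#' @param band band in which `noise_rms` is defined, Hz.
#' @keywords internal
broadband_noise_sd <- function(noise_rms, fs, band = c(300, 5000)) {
  nyq <- fs / 2
  frac <- (min(band[2], nyq) - band[1]) / nyq
  noise_rms / sqrt(frac)
}

## ---- ground-truth neurons --------------------------------------------------

#' Generate a ground-truth neuron with a branching axonal arbor
#'
#' Branches are random walks from the axon initial segment (AIS): points at
#' `step_um` spacing with per-step heading jitter `angle_sd` (radians).
#' Near the bounds the heading is steered smoothly toward the array
#' interior (curvature-limited, no hairpin folds -- axons in culture
#' wander rather than double back on themselves, and a fold would also
#' break the chord-summed path-length estimate downstream).
#' Each branch carries one conduction velocity;
#' the per-point signal amplitude decays linearly from `axon_amp_uv[1]` at
#' the AIS to `axon_amp_uv[2]` at the branch tip (negative peaks). The soma
#' contributes a large negative peak (`soma_amp_uv`) at the AIS.
#'
#' Uses the current R RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param bounds list with `xlim`, `ylim` (um) the arbor must stay inside.
#' @param neuron_id integer id.
#' @param ais AIS position `c(x, y)` um; random inside the bounds if `NULL`.
#' @param n_branches branch count; default draws `1 + rpois(1, 1.5)`.
#' @param velocity_mms per-branch conduction velocity: a single value, a
#'   range `c(lo, hi)` sampled uniformly, or `NULL` for the cortical-culture
#'   default `rnorm(480, 90)` truncated at 100 mm/s.
#' @param branch_length_um range of branch path lengths, um; the default
#'   650-950 um matches longest-branch statistics of mature cortical
#'   cultures on this array class.
#' @param step_um spacing of branch polyline points, um.
#' @param angle_sd heading jitter per step, radians.
#' @param soma_amp_uv soma negative-peak amplitude (uV, < 0).
#' @param axon_amp_uv negative-peak amplitude at branch start and tip
#'   (uV magnitudes, decaying along the branch).
#' @param initial_angle optional initial heading per branch (radians).
#' @return list of class `gt_neuron`.
#' @export
generate_arbor <- function(bounds, neuron_id = 1L, ais = NULL,
                           n_branches = NULL, velocity_mms = NULL,
                           branch_length_um = c(650, 950), step_um = 6,
                           angle_sd = 0.08, soma_amp_uv = -150,
                           axon_amp_uv = c(35, 15), initial_angle = NULL) {
  if (is.null(bounds$xlim) || is.null(bounds$ylim) ||
      diff(bounds$xlim) <= 0 || diff(bounds$ylim) <= 0)
    stop("invalid parameter: empty bounds")
  if (soma_amp_uv >= 0) stop("invalid parameter: soma_amp_uv must be < 0")
  if (is.null(ais)) {
    mx <- min(50, diff(bounds$xlim) / 4)
    my <- min(30, diff(bounds$ylim) / 4)
    ais <- c(stats::runif(1, bounds$xlim[1] + mx, bounds$xlim[2] - mx),
             stats::runif(1, bounds$ylim[1] + my, bounds$ylim[2] - my))
  }
  if (is.null(n_branches)) n_branches <- 1L + stats::rpois(1L, 1.5)
  draw_velocity <- function() {
    if (is.null(velocity_mms)) max(100, stats::rnorm(1, 480, 90))
    else if (length(velocity_mms) == 2L)
      stats::runif(1, velocity_mms[1], velocity_mms[2])
    else velocity_mms
  }
  branches <- vector("list", n_branches)
  for (b in seq_len(n_branches)) {
    v <- draw_velocity()
    if (v <= 0) stop("invalid parameter: velocity must be > 0")
    len <- if (length(branch_length_um) == 2L)
      stats::runif(1, branch_length_um[1], branch_length_um[2])
    else branch_length_um
    n_steps <- max(2L, ceiling(len / step_um))
    th <- if (is.null(initial_angle)) stats::runif(1, 0, 2 * pi)
          else initial_angle[min(b, length(initial_angle))]
    pts <- matrix(NA_real_, n_steps + 1L, 2L)
    pts[1L, ] <- ais
    ctr <- c(mean(bounds$xlim), mean(bounds$ylim))
    margin <- 50
    max_turn <- 0.1                      # rad per step: curvature radius >= 60 um
    for (k in seq_len(n_steps)) {
      th <- th + stats::rnorm(1, 0, angle_sd)
      cur <- pts[k, ]
      to_ctr <- atan2(ctr[2] - cur[2], ctr[1] - cur[1])
      turn_dir <- sign(atan2(sin(to_ctr - th), cos(to_ctr - th)))
      if (turn_dir == 0) turn_dir <- 1
      dwall <- min(cur[1] - bounds$xlim[1], bounds$xlim[2] - cur[1],
                   cur[2] - bounds$ylim[1], bounds$ylim[2] - cur[2])
      if (dwall < margin)                # soft steering away from the wall
        th <- th + turn_dir * max_turn * (1 - max(0, dwall) / margin)
      nxt <- cur + step_um * c(cos(th), sin(th))
      tries <- 0L
      while ((nxt[1] < bounds$xlim[1] || nxt[1] > bounds$xlim[2] ||
              nxt[2] < bounds$ylim[1] || nxt[2] > bounds$ylim[2]) &&
             tries < 100L) {             # hard steering if still outside
        th <- th + turn_dir * max_turn
        nxt <- cur + step_um * c(cos(th), sin(th))
        tries <- tries + 1L
      }
      pts[k + 1L, ] <- nxt
    }
    cumdist <- step_um * (0:n_steps)
    amp <- -seq(axon_amp_uv[1], axon_amp_uv[2], length.out = n_steps + 1L)
    branches[[b]] <- list(points = pts, cumdist_um = cumdist,
                          velocity_mms = v, amp_uv = amp)
  }
  structure(list(neuron_id = as.integer(neuron_id), ais = ais,
                 soma_amp_uv = soma_amp_uv, branches = branches),
            class = "gt_neuron")
}

#' Ground-truth electrode hits of a neuron
#'
#' For every electrode that sees any source point of the neuron above
#' `min_amp_uv` (after [spatial_decay()]), the dominant (largest-amplitude)
#' source determines the electrode's amplitude and true arrival latency
#' (path distance / branch velocity; 0 for the soma). Per-branch rows are
#' returned so branch-wise recovery can be scored.
#'
#' @param neuron a `gt_neuron`.
#' @param array an `electrode_array`.
#' @param lambda_um spatial decay constant.
#' @param min_amp_uv amplitude floor below which a source is invisible, uV.
#' @return data.frame with columns `neuron`, `branch` (0 = soma),
#'   `electrode`, `amp_uv` (negative), `latency_ms`, `dominant` (logical:
#'   largest-amplitude source for that electrode).
#' @export
neuron_hits <- function(neuron, array, lambda_um = 10, min_amp_uv = 1) {
  pos <- electrode_positions(array)
  srcs <- list(list(branch = 0L, pts = matrix(neuron$ais, 1L),
                    amp = neuron$soma_amp_uv, lat_ms = 0))
  for (b in seq_along(neuron$branches)) {
    br <- neuron$branches[[b]]
    # um / (mm/s) = um / (um/ms) = ms
    srcs[[b + 1L]] <- list(branch = b, pts = br$points, amp = br$amp_uv,
                           lat_ms = br$cumdist_um / br$velocity_mms)
  }
  out <- vector("list", length(srcs))
  for (s in seq_along(srcs)) {
    src <- srcs[[s]]
    # electrodes possibly above the floor: prune by bounding box
    max_r <- lambda_um * (max(abs(src$amp)) / min_amp_uv - 1)
    bb <- apply(src$pts, 2L, range)
    cand <- which(pos[, 1] >= bb[1, 1] - max_r & pos[, 1] <= bb[2, 1] + max_r &
                  pos[, 2] >= bb[1, 2] - max_r & pos[, 2] <= bb[2, 2] + max_r)
    if (!length(cand)) { out[[s]] <- NULL; next }
    d2 <- outer(pos[cand, 1], src$pts[, 1], "-")^2 +
          outer(pos[cand, 2], src$pts[, 2], "-")^2
    # per electrode: the source point with the largest delivered amplitude
    av <- sweep(1 / (1 + sqrt(d2) / lambda_um), 2L, abs(src$amp), "*")
    jbest <- max.col(av, ties.method = "first")
    abest <- av[cbind(seq_along(cand), jbest)]
    keep <- abest >= min_amp_uv
    if (!any(keep)) { out[[s]] <- NULL; next }
    out[[s]] <- data.frame(
      neuron = neuron$neuron_id, branch = src$branch,
      electrode = array$ids[cand[keep]],
      amp_uv = -abest[keep],
      latency_ms = src$lat_ms[jbest[keep]])
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    return(data.frame(neuron = integer(0), branch = integer(0),
                      electrode = integer(0), amp_uv = numeric(0),
                      latency_ms = numeric(0), dominant = logical(0)))
  o <- order(hits$electrode, hits$amp_uv)  # most negative amp first per electrode
  hits <- hits[o, ]
  hits$dominant <- !duplicated(hits$electrode)
  rownames(hits) <- NULL
  hits
}

## ---- network spiking -------------------------------------------------------

#' Network spiking specification
#'
#' Baseline Poisson firing modulated by population bursts, plus pairwise
#' monosynaptic couplings: each presynaptic spike elicits a postsynaptic
#' spike at `+latency_ms` with probability `prob`. Defaults reflect mature
#' cortical cultures: mean rate 2.4 Hz, bursts of ~0.8 s every ~6.5 s.
#'
#' @param n_neurons number of units.
#' @param rate_hz baseline firing rate(s), Hz (scalar or per neuron).
#' @param connections data.frame `pre`, `post`, `latency_ms`, `prob`
#'   (1-based unit indices); `NULL` for none.
#' @param burst_rate_hz rate of burst onsets (Poisson), per second.
#' @param burst_duration_s burst length, seconds.
#' @param burst_gain firing-rate multiplier inside bursts (1 = no bursts).
#' @return list of class `network_spec`.
#' @export
network_spec <- function(n_neurons, rate_hz = 2.4, connections = NULL,
                         burst_rate_hz = 0.15, burst_duration_s = 0.8,
                         burst_gain = 8) {
  if (!is.null(connections)) {
    stopifnot(all(c("pre", "post", "latency_ms", "prob") %in% names(connections)))
    if (any(connections$prob < 0 | connections$prob > 1))
      stop("invalid parameter: probabilities must be in [0, 1]")
    if (any(connections$latency_ms <= 0))
      stop("invalid parameter: latencies must be > 0")
  }
  structure(list(n_neurons = as.integer(n_neurons),
                 rate_hz = rep_len(rate_hz, n_neurons),
                 connections = connections,
                 burst_rate_hz = burst_rate_hz,
                 burst_duration_s = burst_duration_s,
                 burst_gain = burst_gain),
            class = "network_spec")
}

#' Generate coupled spike trains
#'
#' Inhomogeneous-Poisson baseline (rate multiplied by `burst_gain` inside
#' burst windows), then synaptic transmission: for each connection, every
#' presynaptic spike is copied to the postsynaptic train at `+latency_ms`
#' with probability `prob`. Trains are sorted and clipped to
#' `[0, duration)`.
#'
#' @param spec a [network_spec()].
#' @param duration_s recording duration, seconds.
#' @return named list of sorted spike-time vectors (`"1"`, `"2"`, ...);
#'   attribute `burst_windows` holds the true burst onset/offset matrix.
#' @export
generate_network_spikes <- function(spec, duration_s) {
  if (duration_s < 0) stop("invalid parameter: negative duration")
  # burst windows (possibly overlapping; merged)
  wins <- matrix(numeric(0), 0L, 2L)
  if (spec$burst_gain > 1 && spec$burst_rate_hz > 0) {
    n_b <- stats::rpois(1L, spec$burst_rate_hz * duration_s)
    if (n_b > 0) {
      on <- sort(stats::runif(n_b, 0, duration_s))
      off <- pmin(on + spec$burst_duration_s, duration_s)
      keep <- rep(TRUE, n_b)
      for (k in seq_len(n_b - 1L) + 1L)
        if (on[k] < off[k - 1L]) { off[k - 1L] <- off[k]; keep[k] <- FALSE }
      wins <- cbind(on[keep], off[keep])
    }
  }
  in_burst_frac <- if (nrow(wins)) sum(wins[, 2] - wins[, 1]) / duration_s else 0
  trains <- vector("list", spec$n_neurons)
  for (i in seq_len(spec$n_neurons)) {
    r <- spec$rate_hz[i]
    # piecewise-homogeneous Poisson: baseline everywhere + extra inside bursts
    n_base <- stats::rpois(1L, r * duration_s)
    t <- stats::runif(n_base, 0, duration_s)
    if (nrow(wins) && spec$burst_gain > 1) {
      extra_rate <- r * (spec$burst_gain - 1)
      for (w in seq_len(nrow(wins))) {
        n_w <- stats::rpois(1L, extra_rate * (wins[w, 2] - wins[w, 1]))
        t <- c(t, stats::runif(n_w, wins[w, 1], wins[w, 2]))
      }
    }
    trains[[i]] <- sort(t)
  }
  if (!is.null(spec$connections)) {
    cn <- spec$connections
    for (k in seq_len(nrow(cn))) {
      pre <- trains[[cn$pre[k]]]
      if (!length(pre)) next
      sent <- pre[stats::runif(length(pre)) < cn$prob[k]] + cn$latency_ms[k] / 1000
      sent <- sent[sent < duration_s]
      trains[[cn$post[k]]] <- sort(c(trains[[cn$post[k]]], sent))
    }
  }
  names(trains) <- as.character(seq_len(spec$n_neurons))
  attr(trains, "burst_windows") <- wins
  trains
}

## ---- rendering -------------------------------------------------------------

# Duplicate-safe accumulation x[i] <- x[i] + v without rowsum's
# rowname overhead: repeated passes over the duplicated remainder
# (multiplicity is tiny -- overlapping windows on one trace are rare).
accumulate_at <- function(x, i, v) {
  while (length(i)) {
    d <- duplicated(i)
    x[i[!d]] <- x[i[!d]] + v[!d]
    i <- i[d]; v <- v[d]
  }
  x
}

# Sample indices and values of `template(t - times[j]) * amp[j]` on a
# trace of n samples at rate fs.
template_event_samples <- function(n, fs, times, amp, template) {
  dur <- attr(template, "duration_s")
  L <- ceiling(dur * fs) + 1L
  amp <- rep_len(amp, length(times))
  i0 <- floor(times * fs) + 1L           # first sample index at/after onset
  idx <- outer(i0, 0:L, "+")             # events x samples
  rel <- (idx - 1) / fs - times          # recycles times down columns
  val <- template(rel) * amp
  ok <- idx >= 1L & idx <= n & val != 0
  list(idx = idx[ok], val = val[ok])
}

# Add `template(t - times[j]) * amp[j]` into trace x sampled at fs.
add_template_events <- function(x, fs, times, amp, template) {
  if (!length(times)) return(x)
  ev <- template_event_samples(length(x), fs, times, amp, template)
  accumulate_at(x, ev$idx, ev$val)
}

#' Render a dual-mode recording from ground-truth neurons and spikes
#'
#' For every spike of every neuron, the biphasic waveform template, scaled
#' by the electrode's ground-truth amplitude, is added at
#' `spike time + arrival latency` to both streams (each sampled at its own
#' rate from the same continuous signal model). Independent white Gaussian
#' noise, scaled so its 0.3-5 kHz band rms equals each mode's `noise_rms`,
#' is then added per stream.
#'
#' @param neurons list of `gt_neuron`s.
#' @param spike_trains list of spike-time vectors (seconds), one per neuron.
#' @param array an `electrode_array`.
#' @param duration_s recording duration.
#' @param aps_params,sm_params per-stream [mode_params()].
#' @param sm_electrodes electrode ids routed to the high-SNR stream.
#' @param template waveform template, see [biphasic_template()].
#' @param lambda_um,min_amp_uv spatial decay model, see [neuron_hits()].
#' @param noise logical; add noise (FALSE gives the noiseless signal model).
#' @param t0 clock origin, seconds.
#' @return list with `recording` (a `dual_mode_recording`, spike trains
#'   attached as units) and `truth` (list: `neurons`, `hits` table,
#'   `spike_trains`, `burst_windows` if present).
#' @export
render_recording <- function(neurons, spike_trains, array, duration_s,
                             aps_params = mode_params("full_frame"),
                             sm_params = mode_params("high_snr"),
                             sm_electrodes = integer(0),
                             template = biphasic_template(),
                             lambda_um = 10, min_amp_uv = 1,
                             noise = TRUE, t0 = 0) {
  if (!all(sm_electrodes %in% array$ids))
    stop("invalid parameter: sm_electrodes outside array")
  n_e <- n_electrodes(array)
  n_f <- as.integer(round(duration_s * aps_params$sampling_rate))
  aps <- matrix(0, n_e, n_f)
  n_sm <- as.integer(round(duration_s * sm_params$sampling_rate))
  sm <- if (length(sm_electrodes)) matrix(0, length(sm_electrodes), n_sm)
  sm_row <- match(as.integer(sm_electrodes), array$ids)

  hits_all <- vector("list", length(neurons))
  for (k in seq_along(neurons)) {
    nrn <- neurons[[k]]
    hits <- neuron_hits(nrn, array, lambda_um, min_amp_uv)
    hits_all[[k]] <- hits
    dom <- hits[hits$dominant, , drop = FALSE]
    if (!nrow(dom)) {
      warning("neuron ", nrn$neuron_id, " produces no in-bounds signal")
      next
    }
    spk <- spike_trains[[k]]
    if (!length(spk)) next
    aidx <- vector("list", nrow(dom)); aval <- vector("list", nrow(dom))
    for (h in seq_len(nrow(dom))) {
      row <- match(dom$electrode[h], array$ids)
      tt <- spk + dom$latency_ms[h] / 1000
      # template has unit NEGATIVE peak; scale by the amplitude magnitude
      # so the rendered negative peak equals amp_uv
      ev <- template_event_samples(n_f, aps_params$sampling_rate, tt,
                                   abs(dom$amp_uv[h]), template)
      aidx[[h]] <- (ev$idx - 1) * n_e + row   # column-major linear index
      aval[[h]] <- ev$val
      srow <- match(row, sm_row)
      if (!is.na(srow))
        sm[srow, ] <- add_template_events(sm[srow, ], sm_params$sampling_rate,
                                          tt, abs(dom$amp_uv[h]), template)
    }
    ii <- unlist(aidx); vv <- unlist(aval)
    while (length(ii)) {        # inline duplicate-pass add: no matrix copy
      d <- duplicated(ii)
      aps[ii[!d]] <- aps[ii[!d]] + vv[!d]
      ii <- ii[d]; vv <- vv[d]
    }
  }
  if (noise) {
    # column blocks keep temporaries small on full-array matrices; inline
    # so the big matrices are modified without a function-call copy
    sd_aps <- broadband_noise_sd(aps_params$noise_rms, aps_params$sampling_rate)
    blk <- max(1L, 5e6 %/% n_e)
    for (j0 in seq(1L, n_f, by = blk)) {
      j1 <- min(j0 + blk - 1L, n_f)
      aps[, j0:j1] <- aps[, j0:j1] + stats::rnorm(n_e * (j1 - j0 + 1L), 0, sd_aps)
    }
    if (!is.null(sm)) {
      sd_sm <- broadband_noise_sd(sm_params$noise_rms, sm_params$sampling_rate)
      blk <- max(1L, 5e6 %/% nrow(sm))
      for (j0 in seq(1L, n_sm, by = blk)) {
        j1 <- min(j0 + blk - 1L, n_sm)
        sm[, j0:j1] <- sm[, j0:j1] +
          stats::rnorm(nrow(sm) * (j1 - j0 + 1L), 0, sd_sm)
      }
    }
  }
  names(spike_trains) <- names(spike_trains) %||%
    as.character(seq_along(spike_trains))
  rec <- dual_mode_recording(aps, aps_params, array, sm, sm_params,
                             sm_electrodes, t0 = t0, units = spike_trains)
  truth <- list(neurons = neurons, hits = do.call(rbind, hits_all),
                spike_trains = spike_trains,
                burst_windows = attr(spike_trains, "burst_windows"))
  list(recording = rec, truth = truth)
}

#' Write simulator ground truth next to a recording container
#'
#' Stores arbor polylines and velocities, per-branch electrode hit lists,
#' and the connection table as plain CSV under `<path>/ground_truth/`.
#'
#' @param truth the `truth` element returned by [render_recording()].
#' @param path recording container directory.
#' @param connections optional connection table (`pre`, `post`,
#'   `latency_ms`, `prob`).
#' @export
write_ground_truth <- function(truth, path, connections = NULL) {
  gdir <- file.path(path, "ground_truth")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  br <- do.call(rbind, lapply(truth$neurons, function(n) {
    do.call(rbind, lapply(seq_along(n$branches), function(b) {
      data.frame(neuron = n$neuron_id, branch = b,
                 point = seq_len(nrow(n$branches[[b]]$points)),
                 x_um = n$branches[[b]]$points[, 1],
                 y_um = n$branches[[b]]$points[, 2],
                 cumdist_um = n$branches[[b]]$cumdist_um,
                 amp_uv = n$branches[[b]]$amp_uv,
                 velocity_mms = n$branches[[b]]$velocity_mms)
    }))
  }))
  utils::write.csv(br, file.path(gdir, "branches.csv"), row.names = FALSE)
  som <- do.call(rbind, lapply(truth$neurons, function(n)
    data.frame(neuron = n$neuron_id, ais_x_um = n$ais[1], ais_y_um = n$ais[2],
               soma_amp_uv = n$soma_amp_uv)))
  utils::write.csv(som, file.path(gdir, "neurons.csv"), row.names = FALSE)
  utils::write.csv(truth$hits, file.path(gdir, "hits.csv"), row.names = FALSE)
  if (!is.null(connections))
    utils::write.csv(connections, file.path(gdir, "connections.csv"),
                     row.names = FALSE)
  invisible(path)
}
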