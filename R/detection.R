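#' Detection parameters
#'
#' Defaults follow standard practice for this recording system: 300-3000 Hz
#' action-potential band, detection at 7.5x the (robust) noise standard
#' deviation, electrode preselection above 80 uV, 12 ms footprint template,
#' and a 1-300 Hz preset for local-field potentials.
#'
#' @param band AP band, Hz.
#' @param threshold_k detection threshold in multiples of the noise sd.
#' @param preselect_amp_uv electrode preselection amplitude, uV.
#' @param template_ms spike-triggered-average window length, ms. The whole
#'   window is centred on the trigger (-6/+6 ms by default); a short
#'   `+/-2 ms` window can be requested with `template_ms = 4`.
#' @param lfp_band LFP band preset, Hz.
#' @param refractory_ms crossings closer than this are merged to one event.
#' @export
detection_params <- function(band = c(300, 3000), threshold_k = 7.5,
                             preselect_amp_uv = 80, template_ms = 12,
                             lfp_band = c(1, 300), refractory_ms = 1.5) {
  if (band[1] <= 0 || band[2] <= band[1])
    stop("invalid parameter: need 0 < band[1] < band[2]")
  if (threshold_k <= 0) stop("invalid parameter: threshold_k must be > 0")
  structure(list(band = band, threshold_k = threshold_k,
                 preselect_amp_uv = preselect_amp_uv,
                 template_ms = template_ms, lfp_band = lfp_band,
                 refractory_ms = refractory_ms),
            class = "detection_params")
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so filtered peaks keep their timing.
#'
#' @param x numeric trace (or electrodes x samples matrix; filtered by row).
#' @param band `c(low, high)` Hz, high < Nyquist.
#' @param fs sampling rate, Hz.
#' @return filtered trace of identical shape.
#' @export
bandpass_filter <- function(x, band, fs) {
  if (band[1] <= 0 || band[2] <= band[1])
    stop("invalid parameter: need 0 < band[1] < band[2]")
  if (band[2] >= fs / 2)
    stop("invalid parameter: band upper edge must be below Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- signal::filtfilt(bf, x[i, ])
    out
  } else signal::filtfilt(bf, x)
}

#' Robust noise standard deviation
#'
#' `median(|x|) / 0.6745`: the Gaussian-consistent median estimator, which
#' (unlike the plain standard deviation) is not inflated by the spikes
#' riding on the noise.
#'
#' @param x numeric trace.
#' @export
robust_std <- function(x) stats::median(abs(x)) / 0.6745

#' Detect negative-threshold spike events on one trace
#'
#' Expects a band-passed trace. Samples below `-threshold_k * sd` are
#' grouped (crossings within `refractory_ms` belong to one event) and each
#' event is timed at its minimum sample.
#'
#' @param x band-passed trace, uV.
#' @param fs sampling rate, Hz.
#' @param threshold_k threshold in noise-sd multiples.
#' @param refractory_ms grouping window, ms.
#' @param t0 clock origin of the trace, seconds.
#' @param noise_sd noise sd; estimated with [robust_std()] if `NULL`.
#' @return numeric vector of event times (seconds); attribute
#'   `threshold_uv` records the threshold used.
#' @export
detect_spikes <- function(x, fs, threshold_k = 7.5, refractory_ms = 1.5,
                          t0 = 0, noise_sd = NULL) {
  if (length(x) < 2L) {
    warning("trace shorter than one template; no detection")
    return(numeric(0))
  }
  if (is.null(noise_sd)) noise_sd <- robust_std(x)
  thr <- -threshold_k * noise_sd
  below <- which(x < thr)
  if (!length(below)) {
    out <- numeric(0); attr(out, "threshold_uv") <- -thr; return(out)
  }
  gap <- as.integer(round(refractory_ms / 1000 * fs))
  grp <- cumsum(c(1L, diff(below) > gap))
  idx <- vapply(split(below, grp),
                function(i) i[which.min(x[i])], integer(1))
  out <- t0 + (unname(idx) - 1) / fs
  attr(out, "threshold_uv") <- -thr
  out
}

#' Preselect electrodes by filtered signal amplitude
#'
#' Electrodes whose band-passed full-frame trace shows a negative peak
#' larger than `preselect_amp_uv` (the preselection that reduces a
#' full-array recording to the ~1000-1500 channels worth spike sorting).
#'
#' @param rec a `dual_mode_recording`.
#' @param params [detection_params()].
#' @return integer vector of electrode ids.
#' @export
preselect_electrodes <- function(rec, params = detection_params()) {
  fs <- rec$aps_params$sampling_rate
  filt <- bandpass_filter(rec$aps, params$band, fs)
  peak <- -apply(filt, 1L, min)
  rec$array$ids[peak > params$preselect_amp_uv]
}

#' Map trigger times onto full-frame frame indices
#'
#' Both streams share one clock origin, but their rates are not integer
#' multiples; alignment is by timestamps. Each trigger time is mapped to
#' the nearest full-frame frame (0-based), with mapping error at most half
#' a frame period (43.1 us at 11.6 kHz). Triggers outside the stream span
#' are dropped and counted.
#'
#' @param times trigger times, seconds (same clock as the recording).
#' @param fs full-frame sampling rate, Hz.
#' @param n_frames number of full-frame frames.
#' @param t0 clock origin of the full-frame stream, seconds.
#' @return integer frame indices (0-based); attribute `n_dropped`.
#' @export
align_triggers <- function(times, fs, n_frames, t0 = 0) {
  fr <- as.integer(round((times - t0) * fs))
  ok <- fr >= 0L & fr < n_frames
  out <- fr[ok]
  attr(out, "n_dropped") <- sum(!ok)
  if (any(!ok)) message(sum(!ok), " trigger(s) outside the stream span dropped")
  out
}

#' Spike-triggered average and electrical footprint
#'
#' Averages full-frame windows of `template_ms` centred on the trigger
#' frames, per electrode. This suppresses uncorrelated noise as 1/sqrt(N)
#' and makes signals visible that are far below the single-frame detection
#' limit; with triggers extracted from the simultaneously recorded low-noise
#' stream, footprints of units invisible to direct full-frame detection can
#' be reconstructed.
#'
#' For each electrode the footprint records the negative-peak amplitude,
#' the peak latency relative to the initiation site (the largest-amplitude
#' electrode; ties broken toward the smaller id), and a peak-time
#' dispersion ("jitter"). Single-window peak times are meaningless at
#' axonal signal-to-noise, so jitter is estimated from sub-averages of
#' `jitter_group` triggers (at least 6 groups), with the per-group peak
#' search confined to `+/- jitter_search_ms` around the electrode's
#' footprint peak; `jitter_group = 1` gives the literal per-event peak-time
#' standard deviation.
#'
#' @param aps electrodes x frames matrix, uV (raw full-frame stream).
#' @param fs full-frame sampling rate, Hz.
#' @param triggers 0-based trigger frame indices (see [align_triggers()]).
#' @param array `electrode_array` matching the rows of `aps`.
#' @param template_ms window length, ms (window is centred on the trigger).
#' @param unit_id identifier stored with the footprint.
#' @param jitter_group target sub-average group size for jitter estimation.
#' @param jitter_search_ms half-width of the per-group peak search, ms.
#' @return object of class `footprint`: list with `table` (data.frame
#'   `id, x, y, amplitude_uv, peak_frame, latency_ms, jitter_ms`),
#'   `waveforms` (electrodes x samples, uV), `fs`, `n_triggers`,
#'   `init_id`, `template_ms`.
#' @export
spike_triggered_average <- function(aps, fs, triggers, array,
                                    template_ms = 12, unit_id = NA,
                                    jitter_group = 50, jitter_search_ms = 2) {
  half <- as.integer(round(template_ms / 2 * fs / 1000))
  L <- 2L * half + 1L
  n <- ncol(aps)
  tr <- triggers[triggers - half >= 0L & triggers + half <= n - 1L]
  if (!length(tr)) stop("empty footprint: no trigger fully inside the recording")
  n_e <- nrow(aps)
  g <- max(1L, min(as.integer(jitter_group), length(tr) %/% 6L))
  n_groups <- max(1L, length(tr) %/% g)
  grp_of <- pmin(((seq_along(tr) - 1L) %/% g) + 1L, n_groups)
  gn <- tabulate(grp_of, n_groups)
  # one pass per window offset; trigger / group sums via one matrix product
  W <- matrix(0, length(tr), n_groups + 1L)
  W[, 1L] <- 1
  W[cbind(seq_along(tr), grp_of + 1L)] <- 1
  acc <- matrix(0, n_e, L)
  gsum <- matrix(0, n_e, L * n_groups)   # group k occupies columns (k-1)*L + 1:L
  gcol <- (seq_len(n_groups) - 1L) * L
  for (o in seq_len(L)) {
    S <- aps[, tr + (o - half), drop = FALSE] %*% W   # tr is 0-based
    acc[, o] <- S[, 1L]
    gsum[, gcol + o] <- S[, -1L]
  }
  wave <- acc / length(tr)
  peak_frame <- max.col(-wave, ties.method = "first")
  amplitude <- -wave[cbind(seq_len(n_e), peak_frame)]
  init <- which.max(amplitude)           # first max = smallest id
  latency_ms <- (peak_frame - peak_frame[init]) / fs * 1000
  # sub-sample peak refinement (parabola through the peak and neighbours);
  # the tracker itself stays frame-based, but the refined latency is kept
  # for the optional interpolated velocity fit
  pf <- pmin(pmax(peak_frame, 2L), L - 1L)
  ym <- wave[cbind(seq_len(n_e), pf - 1L)]
  y0 <- wave[cbind(seq_len(n_e), pf)]
  yp <- wave[cbind(seq_len(n_e), pf + 1L)]
  den <- ym - 2 * y0 + yp
  delta <- ifelse(abs(den) > 1e-12, 0.5 * (ym - yp) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  frame_interp <- pf + delta
  latency_interp_ms <- (frame_interp - frame_interp[init]) / fs * 1000
  ## jitter from group sub-averages
  jitter_ms <- rep(NA_real_, n_e)
  if (n_groups >= 2L) {
    s <- max(1L, as.integer(round(jitter_search_ms / 1000 * fs)))
    offs <- -s:s
    cols <- outer(peak_frame, offs, "+")
    cols[cols < 1L] <- 1L
    cols[cols > L] <- L
    gather <- cbind(rep(seq_len(n_e), times = length(offs)), as.vector(cols))
    pk <- matrix(NA_real_, n_e, n_groups)
    for (k in seq_len(n_groups)) {
      gm <- gsum[, (k - 1L) * L + seq_len(L), drop = FALSE] / gn[k]
      vals <- matrix(gm[gather], n_e, length(offs))
      pk[, k] <- offs[max.col(-vals, ties.method = "first")]
    }
    jitter_ms <- apply(pk, 1L, stats::sd) / fs * 1000
  }
  tab <- data.frame(id = array$ids, x = array$x, y = array$y,
                    amplitude_uv = amplitude,
                    peak_frame = peak_frame - 1L,   # 0-based within window
                    latency_ms = latency_ms,
                    latency_interp_ms = latency_interp_ms,
                    jitter_ms = jitter_ms)
  structure(list(unit_id = unit_id, table = tab, waveforms = wave, fs = fs,
                 template_ms = template_ms, n_triggers = length(tr),
                 init_id = array$ids[init]),
            class = "footprint")
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint> unit %s: %d electrodes, %d triggers, max %.1f uV at electrode %d\n",
              as.character(x$unit_id), nrow(x$table), x$n_triggers,
              max(x$table$amplitude_uv), x$init_id))
  invisible(x)
}

#' Whole-sample activity map
#'
#' Per-electrode largest negative-peak amplitude of the band-passed
#' full-frame trace and the rate of threshold crossings. Use
#' `band = c(1, 300)` for a local-field-potential map.
#'
#' @param rec a `dual_mode_recording`.
#' @param band filter band, Hz (AP preset 300-3000 by default).
#' @param threshold_k event threshold in noise-sd multiples.
#' @return data.frame `id, amplitude_uv, rate_hz`.
#' @export
activity_map <- function(rec, band = c(300, 3000), threshold_k = 7.5) {
  fs <- rec$aps_params$sampling_rate
  dur <- recording_duration(rec)
  filt <- bandpass_filter(rec$aps, band, fs)
  amp <- -apply(filt, 1L, min)
  rate <- vapply(seq_len(nrow(filt)), function(i)
    length(detect_spikes(filt[i, ], fs, threshold_k)) / dur, numeric(1))
  data.frame(id = rec$array$ids, amplitude_uv = amp, rate_hz = rate)
}

#' Extract triggers from the low-noise stream of a recording
#'
#' Band-pass filters one high-SNR channel, detects negative-threshold
#' events, and returns their times on the shared clock, ready for
#' [align_triggers()] / [spike_triggered_average()]. This is the dual-mode
#' mechanism: units too small for direct full-frame detection still yield
#' clean triggers on the low-noise stream.
#'
#' @param rec a `dual_mode_recording` with a high-SNR stream.
#' @param electrode electrode id (must be in `rec$sm_electrodes`).
#' @param params [detection_params()].
#' @return spike times in seconds.
#' @export
detect_sm_triggers <- function(rec, electrode, params = detection_params()) {
  row <- match(as.integer(electrode), rec$sm_electrodes)
  if (is.na(row)) stop("unknown electrode id in high-SNR stream: ", electrode)
  fs <- rec$sm_params$sampling_rate
  x <- bandpass_filter(rec$sm[row, ], params$band, fs)
  detect_spikes(x, fs, params$threshold_k, params$refractory_ms, t0 = rec$t0)
}
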