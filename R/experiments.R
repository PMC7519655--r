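#' Arbor and velocity parameter-recovery experiment
#'
#' End-to-end validation of the tracing stage on simulated ground truth:
#' arbors with known per-neuron conduction velocity are rendered into noisy
#' full-frame recordings, footprints are rebuilt by spike-triggered
#' averaging, cleaned, traced, and the recovered velocity and total arbor
#' extension are compared to the truth.
#'
#' Several neurons share one rendered recording (units spike
#' asynchronously, so one unit's spike-triggered average cancels the
#' others' signals like noise); this keeps the experiment fast without
#' changing what is measured. The ground-truth reference for the total
#' extension excludes the stop region next to the initiation site
#' (`velocity * stop_frames * frame period`), which the tracker skips by
#' design.
#'
#' @param n_neurons number of simulated neurons.
#' @param velocity_range per-neuron conduction velocity, uniform, mm/s.
#' @param n_spikes spikes averaged per neuron.
#' @param neurons_per_recording neurons rendered into each recording.
#' @param array the sub-array to simulate on.
#' @param branch_range branch count range per neuron.
#' @param noise add full-frame noise (10.4 uV rms in the AP band).
#' @param cleaning,tracing stage parameters.
#' @param interp use interpolated latencies for the velocity fit.
#' @return data.frame with one row per neuron: `velocity_true_mms`,
#'   `velocity_est_mms`, `n_branches`, `n_segments`, `total_um`,
#'   `total_ref_um`, `velocity_rel_err`, `extension_rel_err`.
#' @export
arbor_recovery_experiment <- function(n_neurons = 50,
                                      velocity_range = c(300, 700),
                                      n_spikes = 300,
                                      neurons_per_recording = 5,
                                      array = hex_array(32, 64),
                                      branch_range = c(1L, 2L),
                                      noise = TRUE,
                                      cleaning = cleaning_params(),
                                      tracing = tracing_params(),
                                      interp = FALSE) {
  bounds <- list(xlim = range(array$x), ylim = range(array$y))
  aps <- mode_params("full_frame")
  fs <- aps$sampling_rate
  frame_ms <- 1000 / fs
  # ISIs: 13.5 ms floor (own windows never overlap the 12 ms template)
  # plus exponential jitter so co-rendered units decohere and average out
  # of each other's spike-triggered mean
  isi_floor <- 0.0135
  isi_jitter <- 0.002
  dur <- 0.05 + n_spikes * (isi_floor + isi_jitter) + 3 * isi_jitter * sqrt(n_spikes)
  rows <- list()
  batches <- split(seq_len(n_neurons),
                   ceiling(seq_len(n_neurons) / neurons_per_recording))
  for (batch in batches) {
    neurons <- list(); trains <- list(); v_true <- numeric(0)
    for (k in seq_along(batch)) {
      v <- stats::runif(1, velocity_range[1], velocity_range[2])
      v_true[k] <- v
      nb <- sample(seq(branch_range[1], branch_range[2]), 1L)
      neurons[[k]] <- generate_arbor(bounds, neuron_id = batch[k],
                                     n_branches = nb, velocity_mms = v)
      trains[[k]] <- 0.05 +
        cumsum(isi_floor + stats::rexp(n_spikes, 1 / isi_jitter))
    }
    rend <- render_recording(neurons, trains, array, dur,
                             aps_params = aps, noise = noise)
    for (k in seq_along(batch)) {
      tr <- align_triggers(trains[[k]] + attr(biphasic_template(), "peak_s"),
                           fs, ncol(rend$recording$aps))
      fp <- spike_triggered_average(rend$recording$aps, fs, tr, array,
                                    unit_id = batch[k])
      cfp <- clean_footprint(fp, params = cleaning)
      segs <- extract_all_segments(cfp, tracing)
      vels <- vapply(segs, function(s)
        fit_velocity(s, interp = interp)[["velocity_mms"]], numeric(1))
      v_est <- if (any(!is.na(vels))) mean(vels, na.rm = TRUE) else NA_real_
      total <- sum(vapply(segs, function(s) s$length_um, numeric(1)))
      ref <- sum(vapply(neurons[[k]]$branches, function(b)
        max(0, max(b$cumdist_um) -
              b$velocity_mms * tracing$stop_frames * frame_ms), numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = batch[k], velocity_true_mms = v_true[k],
        velocity_est_mms = v_est,
        n_branches = length(neurons[[k]]$branches),
        n_segments = length(segs), total_um = total, total_ref_um = ref,
        velocity_rel_err = (v_est - v_true[k]) / v_true[k],
        extension_rel_err = if (ref > 0) (total - ref) / ref else NA_real_)
    }
    rm(rend)
    gc(FALSE)   # release the batch recording before rendering the next
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spike-triggered-average convergence experiment
#'
#' A unit with a fixed small-amplitude waveform is rendered into
#' full-frame noise; footprints are rebuilt from the first N triggers for
#' increasing N and compared to the noiseless render with identical
#' triggers, isolating the averaged-noise residual. The residual rms
#' shrinks as 1/sqrt(N).
#'
#' @param n_list trigger counts to evaluate.
#' @param amp_uv unit soma amplitude (negative peak), uV.
#' @param noise_rms full-frame noise, uV rms in the AP band.
#' @param array small array to render on.
#' @return data.frame `n_triggers`, `residual_rms_uv`; attribute
#'   `loglog_slope` (fitted slope of log residual vs log N).
#' @export
sta_convergence_experiment <- function(n_list = c(10, 30, 100, 300, 1000),
                                       amp_uv = -40, noise_rms = 10.4,
                                       array = hex_array(4, 4)) {
  n_max <- max(n_list)
  bounds <- list(xlim = range(array$x), ylim = range(array$y))
  ctr <- which.min((array$x - mean(array$x))^2 + (array$y - mean(array$y))^2)
  ais <- c(array$x[ctr], array$y[ctr])   # on an electrode: full peak visible
  nrn <- generate_arbor(bounds, ais = ais, n_branches = 1L,
                        velocity_mms = 500, branch_length_um = 30,
                        soma_amp_uv = amp_uv, axon_amp_uv = c(10, 5))
  spacing <- 0.0135
  spk <- seq(0.05, by = spacing, length.out = n_max)
  dur <- 0.05 + n_max * spacing + 0.02
  aps <- mode_params("full_frame", noise_rms = noise_rms)
  fs <- aps$sampling_rate
  clean <- render_recording(list(nrn), list(spk), array, dur,
                            aps_params = aps, noise = FALSE)
  noisy <- render_recording(list(nrn), list(spk), array, dur,
                            aps_params = aps, noise = TRUE)
  tr_all <- align_triggers(spk + attr(biphasic_template(), "peak_s"), fs,
                           ncol(clean$recording$aps))
  res <- vapply(n_list, function(n) {
    tr <- tr_all[seq_len(n)]
    fp_n <- spike_triggered_average(noisy$recording$aps, fs, tr, array)
    fp_c <- spike_triggered_average(clean$recording$aps, fs, tr, array)
    sqrt(mean((fp_n$waveforms - fp_c$waveforms)^2))
  }, numeric(1))
  out <- data.frame(n_triggers = n_list, residual_rms_uv = res)
  slope <- stats::coef(stats::lm(log(res) ~ log(n_list)))[[2L]]
  attr(out, "loglog_slope") <- slope
  out
}

#' Dual-mode footprint recovery experiment
#'
#' The defining mechanism of the dual-mode array: a unit whose amplitude
#' is below the direct full-frame detection limit
#' (`7.5 x 10.4 uV ~ 78 uV` raw threshold scale) is detected on the
#' simultaneously sampled low-noise stream, the trigger times are mapped
#' onto full-frame frames, and spike-triggered averaging recovers its
#' full-frame footprint.
#'
#' @param amp_uv true negative-peak amplitude, uV (must be invisible to
#'   direct full-frame detection).
#' @param n_spikes number of spikes rendered.
#' @param array small array to render on.
#' @return list: `peak_true_uv` (noiseless rendered peak),
#'   `peak_recovered_uv` (dual-mode STA peak), `n_triggers` (SM
#'   detections used), `aps_detections` (direct full-frame detections on
#'   the same electrode -- expected 0), `rel_err`.
#' @export
dual_mode_recovery_experiment <- function(amp_uv = -40, n_spikes = 300,
                                          array = hex_array(8, 8)) {
  bounds <- list(xlim = range(array$x), ylim = range(array$y))
  ctr <- which.min((array$x - mean(array$x))^2 + (array$y - mean(array$y))^2)
  ais <- c(array$x[ctr], array$y[ctr])   # on an electrode: full peak visible
  nrn <- generate_arbor(bounds, ais = ais, n_branches = 1L,
                        velocity_mms = 500, branch_length_um = 40,
                        soma_amp_uv = amp_uv, axon_amp_uv = c(10, 5))
  spacing <- 0.0135
  spk <- seq(0.05, by = spacing, length.out = n_spikes) +
    stats::runif(n_spikes, 0, 0.002)
  dur <- 0.05 + n_spikes * spacing + 0.02
  hits <- neuron_hits(nrn, array)
  best <- hits$electrode[which.min(hits$amp_uv)]
  clean <- render_recording(list(nrn), list(spk), array, dur,
                            sm_electrodes = best, noise = FALSE)
  noisy <- render_recording(list(nrn), list(spk), array, dur,
                            sm_electrodes = best, noise = TRUE)
  fs <- noisy$recording$aps_params$sampling_rate
  ## direct full-frame detection on the best electrode: should fail
  row <- match(best, array$ids)
  aps_filt <- bandpass_filter(noisy$recording$aps[row, ], c(300, 3000), fs)
  n_aps <- length(detect_spikes(aps_filt, fs))
  ## dual-mode path: SM triggers -> full-frame STA
  sm_times <- detect_sm_triggers(noisy$recording, best)
  tr <- align_triggers(sm_times, fs, ncol(noisy$recording$aps))
  fp <- spike_triggered_average(noisy$recording$aps, fs, tr, array)
  ## truth: noiseless render averaged at the true spikes
  tr_true <- align_triggers(spk + attr(biphasic_template(), "peak_s"), fs,
                            ncol(clean$recording$aps))
  fp_true <- spike_triggered_average(clean$recording$aps, fs, tr_true, array)
  pk_true <- max(fp_true$table$amplitude_uv)
  pk_rec <- max(fp$table$amplitude_uv)
  list(peak_true_uv = pk_true, peak_recovered_uv = pk_rec,
       n_triggers = length(tr), aps_detections = n_aps,
       rel_err = abs(pk_rec - pk_true) / pk_true)
}
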