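# Shared fixtures, built in code at test time.

# A footprint object fabricated from an electrode table alone (no
# waveforms); enough for the cleaning / tracing operations, which work on
# the table. Latencies are derived from peak frames like the real STA.
make_footprint <- function(id, x, y, amplitude_uv, peak_frame,
                           jitter_ms = 0, fs = 11600, unit_id = "u1") {
  init <- which.max(amplitude_uv)
  tab <- data.frame(id = as.integer(id), x = x, y = y,
                    amplitude_uv = amplitude_uv,
                    peak_frame = as.integer(peak_frame),
                    latency_ms = (peak_frame - peak_frame[init]) / fs * 1000,
                    jitter_ms = rep_len(jitter_ms, length(id)))
  structure(list(unit_id = unit_id, table = tab, waveforms = NULL, fs = fs,
                 template_ms = 12, n_triggers = 100L,
                 init_id = tab$id[init]),
            class = "footprint")
}

# Straight noiseless axon on a hex sub-array, rendered and averaged.
# Constant axonal amplitude so that cleaning with the given floor keeps
# exactly the on-axis electrode corridor (one electrode column per step).
straight_axon_fixture <- function(velocity_mms = 500, length_um = 800,
                                  n_spikes = 100, axon_amp = 30,
                                  noise = FALSE, frame_aligned = TRUE,
                                  angle = 0, ais_row = 8L, seed = 1) {
  set.seed(seed)
  arr <- hex_array(20, 60)
  bounds <- list(xlim = range(arr$x), ylim = range(arr$y))
  # even row: electrode (ais_row, col 3) at x = 54
  ais <- c(54, ais_row * 18 * sqrt(3) / 2)
  nrn <- generate_arbor(bounds, neuron_id = 1L, ais = ais, n_branches = 1L,
                        velocity_mms = velocity_mms,
                        branch_length_um = length_um, angle_sd = 0,
                        initial_angle = angle, soma_amp_uv = -150,
                        axon_amp_uv = c(axon_amp, axon_amp))
  spk <- if (frame_aligned)               # whole-frame spacing: windows align
    (580 + (seq_len(n_spikes) - 1) * 157) / 11600
  else seq(0.05, by = 0.0135, length.out = n_spikes)
  dur <- max(spk) + 0.02
  rend <- render_recording(list(nrn), list(spk), arr, dur, noise = noise)
  fs <- rend$recording$aps_params$sampling_rate
  tr <- align_triggers(spk + attr(biphasic_template(), "peak_s"), fs,
                       ncol(rend$recording$aps))
  fp <- spike_triggered_average(rend$recording$aps, fs, tr, arr)
  list(array = arr, neuron = nrn, spikes = spk, rend = rend, fp = fp,
       fs = fs)
}

# Two-branch ("Y") arbor fixture, noiseless.
y_arbor_fixture <- function(velocity_mms = 450, seed = 2) {
  set.seed(seed)
  arr <- hex_array(32, 64)
  bounds <- list(xlim = range(arr$x), ylim = range(arr$y))
  ais <- c(108, 16 * 18 * sqrt(3) / 2)
  nrn <- generate_arbor(bounds, neuron_id = 1L, ais = ais, n_branches = 2L,
                        velocity_mms = velocity_mms,
                        branch_length_um = 700, angle_sd = 0,
                        initial_angle = c(0.5, -0.5),
                        axon_amp_uv = c(30, 30))
  spk <- seq(0.05, by = 0.0135, length.out = 50)
  rend <- render_recording(list(nrn), list(spk), arr, 0.8, noise = FALSE)
  fs <- rend$recording$aps_params$sampling_rate
  tr <- align_triggers(spk + attr(biphasic_template(), "peak_s"), fs,
                       ncol(rend$recording$aps))
  fp <- spike_triggered_average(rend$recording$aps, fs, tr, arr)
  list(array = arr, neuron = nrn, rend = rend, fp = fp, fs = fs)
}

# Raster with two high-rate windows calibrated so the 1.35x-baseline
# threshold crossings fall AT the window edges: the smoothed burst profile
# at an edge of a [a, b] window is dR * (PHI(0) - PHI(-(b-a)/sigma)) =
# 0.40879 * dR for a 0.4 s window and sigma = 0.3 s, and the threshold
# excess is 0.35 * baseline. With baseline 3 Hz/unit this gives
# dR * 0.4 / n_units = 1.027 extra spikes per unit per burst, independent
# of n_units. Crossing-to-crossing duration and offset-to-onset IBI then
# equal the constructed 0.4 s and 4.6 s up to kernel/sampling tolerance.
burst_raster_fixture <- function(n_units = 1000, dur = 10,
                                 windows = rbind(c(1.0, 1.4), c(6.0, 6.4)),
                                 base_rate = 3, extra_per_burst = 1.027) {
  lapply(seq_len(n_units), function(i) {
    t <- runif(rpois(1, base_rate * dur), 0, dur)
    for (w in seq_len(nrow(windows)))
      t <- c(t, runif(rpois(1, extra_per_burst), windows[w, 1], windows[w, 2]))
    sort(t)
  })
}

# Ground-truth expected tracker sequence for a noiseless rendering:
# walks backward over quantized true arrival frames, picking per frame the
# largest-amplitude dominant electrode within the search radius --
# computed from simulator truth, independently of the measured footprint.
expected_trace_from_truth <- function(truth, array, fs, params = tracing_params(),
                                      min_amp_uv = 0,
                                      template_peak_s = attr(biphasic_template(), "peak_s")) {
  dom <- truth$hits[truth$hits$dominant, ]
  dom <- dom[abs(dom$amp_uv) > min_amp_uv, ]   # mirrors amplitude cleaning
  frame <- round((dom$latency_ms / 1000 + template_peak_s) * fs)
  init_frame <- frame[which.min(dom$amp_uv)]    # largest |amp| electrode
  pos <- electrode_positions(array, dom$electrode)
  ord <- order(-frame, dom$electrode)
  start <- ord[1L]
  path <- start
  cur <- start
  repeat {
    found <- FALSE
    for (r in seq_len(params$max_gap_frames)) {
      target <- frame[cur] - r
      if (target < init_frame + params$stop_frames) break
      d2 <- (pos[, 1] - pos[cur, 1])^2 + (pos[, 2] - pos[cur, 2])^2
      cand <- which(frame == target & d2 <= (r * params$radius_um + 1e-6)^2)
      if (length(cand)) {
        best <- cand[order(dom$amp_uv[cand], dom$electrode[cand])][1L]
        path <- c(path, best)
        cur <- best
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  dom$electrode[rev(path)]
}
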