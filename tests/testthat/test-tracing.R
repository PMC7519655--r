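# A synthetic footprint of a straight "axon": one electrode per frame,
# amplitudes decaying along the path, soma at the start.
line_footprint <- function(n = 20, spacing_um = 45, jitter_ms = 0,
                           amps = NULL, frames = NULL) {
  if (is.null(amps)) amps <- c(120, seq(30, 12, length.out = n - 1))
  if (is.null(frames)) frames <- seq_len(n) - 1L
  make_footprint(id = seq_len(n) - 1L, x = (seq_len(n) - 1L) * spacing_um,
                 y = rep(0, n), amplitude_uv = amps, peak_frame = frames,
                 jitter_ms = jitter_ms)
}

test_that("cleaning removes low-amplitude and high-jitter electrodes", {
  fp <- make_footprint(id = 0:3, x = c(0, 20, 40, 60), y = rep(0, 4),
                       amplitude_uv = c(100, 5, 30, 25),
                       peak_frame = c(0L, 1L, 2L, 3L),
                       jitter_ms = c(0.1, 0.1, 0.8, 0.69))
  # electrode 1: amplitude 5 uV vs threshold 5.5 * 1.9 = 10.45 uV -> excluded
  # electrode 2: jitter 0.8 ms >= 0.7 ms -> excluded regardless of amplitude
  cfp <- clean_footprint(fp, noise_std = 1.9)
  expect_identical(cfp$table$id, c(0L, 3L))
  # latencies re-referenced to the surviving initiation site
  expect_equal(cfp$table$latency_ms[1], 0)
  # removing everything is a valid empty result, not an error
  empty <- clean_footprint(fp, noise_std = 1000)
  expect_identical(nrow(empty$table), 0L)
  expect_identical(extract_all_segments(empty), list())
})

test_that("noiseless true-signal electrodes all survive cleaning", {
  fx <- straight_axon_fixture(n_spikes = 30)
  dom <- fx$rend$truth$hits[fx$rend$truth$hits$dominant, ]
  # 10% margin for template sampling attenuation of the rendered peak
  strong <- dom$electrode[abs(dom$amp_uv) > 5.5 * 0.5 * 1.1]
  cfp <- clean_footprint(fx$fp, noise_std = 0.5)
  expect_true(all(strong %in% cfp$table$id))
})

test_that("the initiation site is the amplitude maximum, ties to smaller id", {
  fp <- make_footprint(id = c(3L, 7L, 9L), x = c(0, 20, 40), y = rep(0, 3),
                       amplitude_uv = c(50, 80, 80), peak_frame = c(0L, 1L, 2L))
  expect_identical(initiation_site(fp), 7L)
  expect_error(initiation_site(clean_footprint(fp, noise_std = 1e6)),
               "empty footprint")
})

test_that("terminal candidates are delay-map local maxima", {
  fp <- line_footprint()
  expect_identical(terminal_candidates(fp), 19L)        # the far end
  expect_identical(terminal_candidates(fp, assigned = fp$table$id),
                   integer(0))
  # Y arbor: two well-separated tips
  fy <- y_arbor_fixture()
  cfy <- clean_footprint(fy$fp, noise_std = 2.7)
  cands <- terminal_candidates(cfy)
  expect_gte(length(cands), 2L)
})

test_that("backward tracing walks frame by frame choosing the largest amplitude", {
  fp <- line_footprint()
  seg <- trace_segment(fp, 19L)
  # stops 5 frames before the initiation frame (frame 0): first electrode
  # in the path peaks at frame 5
  expect_identical(seg$path$id, 5:19)
  expect_true(all(diff(seg$path$latency_ms) > 0))
  expect_true(all(diff(seg$path$cumdist_um) > 0))
  expect_equal(seg$length_um, 14 * 45)

  # two electrodes share frame 10; the larger amplitude (8 uV) wins
  fp2 <- make_footprint(
    id = 0:12,
    x = c((0:11) * 45, 10 * 45),
    y = c(rep(0, 12), 40),
    amplitude_uv = c(120, seq(30, 14, length.out = 9), 8, 20, 6),
    peak_frame = c(0:11, 10L))
  seg2 <- trace_segment(fp2, 11L)
  expect_true(10L %in% seg2$path$id)      # 8 uV on-path electrode chosen
  expect_false(12L %in% seg2$path$id)     # 6 uV rival in the same frame not
})

test_that("gaps are bridged by widening the search radius", {
  # electrode for frame 6 missing: 120 um jump over 2 frames, allowed
  # because 120 <= 2 x 80 um
  keep <- c(1:6, 8:12)
  fp <- make_footprint(id = keep - 1L, x = (keep - 1L) * 60, y = rep(0, 11),
                       amplitude_uv = c(120, seq(30, 15, length.out = 10)),
                       peak_frame = as.integer(keep - 1L))
  seg <- trace_segment(fp, 11L, tracing_params(radius_um = 80))
  expect_identical(seg$path$id, c(5L, 7L, 8L, 9L, 10L, 11L))
  # with max_gap_frames = 1 the walk cannot cross the gap
  seg1 <- trace_segment(fp, 11L, tracing_params(radius_um = 80,
                                                max_gap_frames = 1))
  expect_identical(seg1$path$id, 7:11)
})

test_that("a start inside the stop region yields a flagged degenerate segment", {
  fp <- line_footprint()
  seg <- trace_segment(fp, 3L)
  expect_true(seg$degenerate)
  expect_identical(nrow(seg$path), 1L)
})

test_that("velocity fits recover the slope of distance versus latency", {
  seg <- structure(list(path = data.frame(
    order = 1:3, id = 0:2, x = c(0, 43.1, 86.2), y = 0,
    latency_ms = c(0, 0.0862, 0.1724), cumdist_um = c(0, 43.1, 86.2))),
    class = "axonal_segment")
  fit <- fit_velocity(seg)
  expect_equal(fit[["velocity_mms"]], 500, tolerance = 1e-6)
  expect_equal(fit[["r_squared"]], 1)
  # reversing the path (re-referenced latencies) gives the same speed
  rev_path <- seg$path
  rev_path$latency_ms <- max(rev_path$latency_ms) - rev(rev_path$latency_ms)
  rev_path$cumdist_um <- max(rev_path$cumdist_um) - rev(rev_path$cumdist_um)
  fit_rev <- fit_velocity(structure(list(path = rev_path),
                                    class = "axonal_segment"))
  expect_equal(fit_rev[["velocity_mms"]], 500, tolerance = 1e-6)
  # degenerate inputs are flagged undefined
  expect_true(is.na(fit_velocity(structure(list(path = seg$path[1:2, ]),
                                           class = "axonal_segment"))[[1]]))
  flat <- seg$path; flat$latency_ms <- 0
  expect_true(is.na(fit_velocity(structure(list(path = flat),
                                           class = "axonal_segment"))[[1]]))
})

test_that("quantized latencies still give velocity within 5%", {
  set.seed(41)
  frame_ms <- 1000 / 11600
  for (k in 1:20) {
    x <- seq(0, 800, by = 43.1)
    lat <- round((x / 500) / frame_ms) * frame_ms
    seg <- structure(list(path = data.frame(
      order = seq_along(x), id = seq_along(x), x = x, y = 0,
      latency_ms = lat, cumdist_um = x)), class = "axonal_segment")
    expect_lt(abs(fit_velocity(seg)[["velocity_mms"]] - 500) / 500, 0.05)
  }
})

test_that("a Y-shaped arbor is traced as two segments covering both branches", {
  fy <- y_arbor_fixture()
  cfy <- clean_footprint(fy$fp, noise_std = 2.7)
  segs <- extract_all_segments(cfy)
  expect_identical(length(segs), 2L)
  # each segment follows one true branch: compare electrode sets with the
  # per-branch ground-truth hits
  hits <- fy$rend$truth$hits
  for (s in segs) {
    on_branch <- vapply(1:2, function(b)
      mean(s$path$id %in% hits$electrode[hits$branch == b]), numeric(1))
    expect_gte(max(on_branch), 0.95)
  }
  # combined traced length covers >= 95% of the traceable truth
  frame_ms <- 1000 / fy$fs
  ref <- sum(vapply(fy$neuron$branches, function(b)
    max(b$cumdist_um) - b$velocity_mms * 5 * frame_ms, numeric(1)))
  total <- sum(vapply(segs, function(s) s$length_um, numeric(1)))
  expect_gt(total / ref, 0.8)
  expect_lt(total / ref, 1.2)
})

test_that("latency is monotone along every traced segment", {
  for (seed in 1:3) {
    set.seed(seed)
    arr <- hex_array(24, 48)
    nrn <- generate_arbor(list(xlim = range(arr$x), ylim = range(arr$y)),
                          n_branches = 2L, velocity_mms = c(350, 650))
    spk <- (580 + (0:39) * 157) / 11600
    rend <- render_recording(list(nrn), list(spk), arr, max(spk) + 0.02,
                             noise = FALSE)
    fs <- rend$recording$aps_params$sampling_rate
    tr <- align_triggers(spk + attr(biphasic_template(), "peak_s"), fs,
                         ncol(rend$recording$aps))
    fp <- spike_triggered_average(rend$recording$aps, fs, tr, arr)
    segs <- extract_all_segments(clean_footprint(fp, noise_std = 0.67))
    expect_gte(length(segs), 1L)
    for (s in segs) {
      expect_true(all(diff(s$path$latency_ms) >= 0))
      expect_true(all(diff(s$path$cumdist_um) > 0))
    }
  }
})

test_that("morphometrics summarize segments, amplitude and firing rate", {
  fp <- line_footprint()
  seg_a <- trace_segment(fp, 19L)
  met <- morphometrics(list(seg_a), fp, spike_times = rep(0.1, 50),
                       duration_s = 25)
  expect_identical(met$n_segments, 1L)
  expect_equal(met$longest_um, seg_a$length_um)
  expect_equal(met$total_um, seg_a$length_um)
  expect_equal(met$max_amp_uv, 120)
  expect_equal(met$rate_hz, 2)
  # two segments: longest vs total
  seg_b <- seg_a; seg_b$length_um <- 300
  met2 <- morphometrics(list(seg_a, seg_b), fp)
  expect_equal(met2$longest_um, seg_a$length_um)
  expect_equal(met2$total_um, seg_a$length_um + 300)
  expect_gte(met2$total_um, met2$longest_um)
  # no segments
  met0 <- morphometrics(list(), fp)
  expect_identical(met0$n_segments, 0L)
  expect_equal(met0$total_um, 0)
  expect_true(is.na(met0$velocity_mms))
})
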