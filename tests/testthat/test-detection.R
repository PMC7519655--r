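test_that("band-pass filter has the expected pass and stop behaviour", {
  fs <- 11600
  t <- (0:(2 * fs - 1)) / fs
  mid <- seq(fs %/% 2, 3 * fs %/% 2)   # avoid edge transients
  pass <- sin(2 * pi * 1000 * t)
  stopb <- sin(2 * pi * 10 * t)
  expect_gte(max(abs(bandpass_filter(pass, c(300, 3000), fs)[mid])), 0.95)
  expect_lte(max(abs(bandpass_filter(stopb, c(300, 3000), fs)[mid])), 0.05)
  expect_equal(bandpass_filter(numeric(500), c(300, 3000), fs), numeric(500))
  expect_error(bandpass_filter(pass, c(300, 6000), fs), "Nyquist")
  expect_error(bandpass_filter(pass, c(3000, 300), fs), "invalid")
})

test_that("robust noise sd matches the Gaussian sd and ignores spikes", {
  set.seed(31)
  x <- rnorm(100000, 0, 7)
  expect_equal(robust_std(x), 7, tolerance = 0.05)
  x[sample(1e5, 500)] <- -300          # 0.5% large events barely move it
  expect_equal(robust_std(x), 7, tolerance = 0.06)
})

test_that("threshold detection finds inserted events and refines to minima", {
  fs <- 24400
  x <- rnorm(fs, 0, 1) * 0           # noiseless
  at <- c(2000, 9000, 20000)
  for (i in at) x[i + 0:4] <- c(-20, -60, -35, -10, -5)
  got <- detect_spikes(x, fs, threshold_k = 7.5, noise_sd = 1)
  expect_equal(round(as.numeric(got) * fs) + 1, at + 1)   # at the -60 uV minimum sample
})

test_that("a 7.5 sigma threshold yields essentially no false positives", {
  set.seed(32)
  fs <- 24400
  x <- bandpass_filter(rnorm(60 * fs, 0, 3), c(300, 3000), fs)
  expect_equal(length(detect_spikes(x, fs, threshold_k = 7.5)), 0L)
})

test_that("-30 uV events on the low-noise stream are all detected", {
  set.seed(33)
  fs <- 24400
  dur <- 10
  at <- sort(sample(seq(0.05, dur - 0.05, by = 0.02), 40))
  x <- rnorm(dur * fs, 0, 3)
  tmpl <- biphasic_template()
  tt <- (0:49) / fs
  for (t0 in at) {
    i <- round(t0 * fs)
    x[i + 1:50] <- x[i + 1:50] + 30 * tmpl(tt)
  }
  xf <- bandpass_filter(x, c(300, 3000), fs)
  got <- detect_spikes(xf, fs, threshold_k = 7.5)
  expect_equal(length(got), length(at))
  expect_true(all(abs(got - (at + attr(tmpl, "peak_s"))) < 0.001))
})

test_that("electrode preselection keeps only large-amplitude channels", {
  arr <- hex_array(6, 6)
  ctr <- 15L
  set.seed(34)
  nrn <- generate_arbor(list(xlim = range(arr$x), ylim = range(arr$y)),
                        ais = c(arr$x[ctr + 1], arr$y[ctr + 1]),
                        n_branches = 1L, velocity_mms = 500,
                        branch_length_um = 30, soma_amp_uv = -120,
                        axon_amp_uv = c(10, 5))
  spk <- seq(0.05, 0.95, by = 0.05)
  rend <- render_recording(list(nrn), list(spk), arr, 1, noise = TRUE)
  sel <- preselect_electrodes(rend$recording)
  expect_true(ctr %in% sel)
  # oracle: per-electrode scan of the filtered negative peak
  fs <- rend$recording$aps_params$sampling_rate
  peaks <- apply(rend$recording$aps, 1, function(x)
    -min(bandpass_filter(x, c(300, 3000), fs)))
  expect_identical(sel, arr$ids[peaks > 80])
  # noise-only recording: nothing reaches 80 uV
  set.seed(35)
  quiet <- render_recording(list(), list(), hex_array(4, 4), 1, noise = TRUE)
  expect_length(preselect_electrodes(quiet$recording), 0L)
})

test_that("trigger times map to the nearest full-frame frame", {
  expect_identical(as.integer(align_triggers(0, 11600, 100)), 0L)
  expect_identical(as.integer(align_triggers(1.0, 11600, 20000)), 11600L)
  set.seed(36)
  t <- runif(1000, 0, 2)
  fr <- align_triggers(t, 11600, 11600 * 2 + 1)
  expect_true(all(abs(fr / 11600 - t) <= 0.5 / 11600 + 1e-12))
  dropped <- align_triggers(c(-0.1, 0.5, 99), 11600, 11600)
  expect_identical(attr(dropped, "n_dropped"), 2L)
  expect_identical(as.integer(dropped), 5800L)
})

test_that("averaging identical noiseless events reproduces the waveform exactly", {
  fx <- straight_axon_fixture(n_spikes = 20)
  # every window is identical, so the average equals any single window
  fs <- fx$fs
  tr <- align_triggers(fx$spikes + attr(biphasic_template(), "peak_s"), fs,
                       ncol(fx$rend$recording$aps))
  half <- (ncol(fx$fp$waveforms) - 1) / 2
  one <- fx$rend$recording$aps[, (tr[5] - half + 1):(tr[5] + half + 1)]
  expect_equal(fx$fp$waveforms, one, tolerance = 1e-12)
  expect_equal(fx$fp$n_triggers, 20L)
  expect_error(spike_triggered_average(fx$rend$recording$aps, fs,
                                       integer(0), fx$array),
               "trigger")
})

test_that("averaging suppresses noise as sigma/sqrt(N)", {
  set.seed(37)
  sc <- sta_convergence_experiment(n_list = c(25, 100))
  # broadband sd is 11.55 uV (10.4 uV in-band); N = 100 -> ~1.16 uV
  expect_lt(sc$residual_rms_uv[2], 1.3)
  expect_gt(sc$residual_rms_uv[1], sc$residual_rms_uv[2])
})

test_that("footprint maps identify the initiation site and relative latency", {
  fx <- straight_axon_fixture(n_spikes = 20)
  tab <- fx$fp$table
  expect_equal(fx$fp$init_id, 483L)       # AIS electrode of the fixture
  expect_equal(tab$latency_ms[tab$id == fx$fp$init_id], 0)
  # latency grows along the axon (on-axis electrodes, row 8)
  ax <- tab[tab$id %in% (8 * 60 + 10:45), ]
  expect_true(all(diff(ax$latency_ms) >= 0))
})

test_that("activity maps peak at the soma and reflect the chosen band", {
  arr <- hex_array(5, 5)
  ctr <- 12L
  set.seed(38)
  nrn <- generate_arbor(list(xlim = range(arr$x), ylim = range(arr$y)),
                        ais = c(arr$x[ctr + 1], arr$y[ctr + 1]),
                        n_branches = 1L, velocity_mms = 500,
                        branch_length_um = 30, soma_amp_uv = -120,
                        axon_amp_uv = c(10, 5))
  spk <- seq(0.05, 0.95, by = 0.1)
  rend <- render_recording(list(nrn), list(spk), arr, 1, noise = TRUE)
  am <- activity_map(rend$recording)
  expect_equal(am$id[which.max(am$amplitude_uv)], ctr)
  expect_gt(am$rate_hz[am$id == ctr], 5)
  # an LFP-band map of a slow oscillation fixture sees it; the AP band does not
  lfp_rec <- rend$recording
  slow <- 40 * sin(2 * pi * 8 * (0:(ncol(lfp_rec$aps) - 1)) / 11600)
  lfp_rec$aps <- matrix(rnorm(length(lfp_rec$aps), 0, 1), nrow(lfp_rec$aps)) +
    rep(slow, each = nrow(lfp_rec$aps))
  am_lfp <- activity_map(lfp_rec, band = c(1, 300))
  am_ap <- activity_map(lfp_rec, band = c(300, 3000))
  expect_true(all(am_lfp$amplitude_uv > 30))
  expect_true(all(am_ap$amplitude_uv < 10))
})
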