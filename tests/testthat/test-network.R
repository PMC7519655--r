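test_that("population rate conserves spike count and has the kernel's shape", {
  expect_equal(population_rate(list(), 10)$rate_hz, numeric(1000))
  # total mass: integral of the smoothed rate equals the spike count
  set.seed(51)
  trains <- lapply(1:20, function(i) sort(runif(100, 2, 8)))
  pr <- population_rate(trains, 10)
  expect_equal(sum(pr$rate_hz) * pr$bin_s, 2000, tolerance = 2000 * 0.001)
  # a single spike becomes a Gaussian bump of sd 0.3 s
  pr1 <- population_rate(list(5.0), 10)
  expect_equal(pr1$t[which.max(pr1$rate_hz)], 5.0, tolerance = 0.011)
  expect_equal(max(pr1$rate_hz), dnorm(0, 0, 0.3), tolerance = 0.01)
  half_dn <- pr1$rate_hz[abs(pr1$t - 5) < 0.301]
  expect_true(all(pr1$rate_hz[abs(pr1$t - 5) > 1.2] < max(pr1$rate_hz) / 100))
})

test_that("a constructed raster yields exactly two bursts with the right timing", {
  set.seed(52)
  trains <- burst_raster_fixture(n_units = 500)
  pr <- population_rate(trains, 10)
  bd <- detect_bursts(pr)
  expect_identical(nrow(bd$bursts), 2L)
  expect_lt(max(abs(bd$bursts$peak_s - c(1.2, 6.2))), 0.2)
  expect_length(bd$ibis_s, 1L)
  expect_lt(abs(bd$ibis_s - 4.6), 0.3)
  # onset-to-onset convention
  bd_on <- detect_bursts(pr, ibi = "onset")
  expect_lt(abs(bd_on$ibis_s - 5.0), 0.3)
})

test_that("burst detection is invariant to unit relabeling and time shifts", {
  set.seed(53)
  trains <- burst_raster_fixture(n_units = 400, dur = 20,
                                 windows = rbind(c(3, 3.4), c(12, 12.4)))
  pr <- detect_bursts(population_rate(trains, 20))
  expect_identical(nrow(pr$bursts), 2L)
  pr_perm <- detect_bursts(population_rate(sample(trains), 20))
  expect_identical(pr$bursts, pr_perm$bursts)
  # uniform translation: the flat baseline level (hence the median
  # threshold) is unchanged, so crossings shift by exactly the offset
  shifted <- lapply(trains, function(t) t + 2)
  pr_sh <- detect_bursts(population_rate(shifted, 22))
  expect_identical(nrow(pr_sh$bursts), 2L)
  expect_lt(max(abs(pr_sh$bursts$onset_s - (pr$bursts$onset_s + 2))), 0.06)
  expect_lt(max(abs(pr_sh$ibis_s - pr$ibis_s)), 0.1)
})

test_that("an unmodulated raster has no bursts above 1.35x its own median", {
  set.seed(54)
  trains <- lapply(1:50, function(i) sort(runif(200, 0, 50)))
  bd <- detect_bursts(population_rate(trains, 50))
  expect_identical(nrow(bd$bursts), 0L)
})

test_that("CCG counts equal exhaustive pair enumeration", {
  set.seed(55)
  for (k in 1:5) {
    a <- sort(runif(500, 0, 60))
    b <- sort(runif(400, 0, 60))
    cc <- compute_ccg(a, b)
    expect_identical(sum(cc$counts), length(which(abs(outer(b, a, "-")) <= 0.0505)))
    expect_equal(cc$counts, oracle_ccg_counts(a, b))
    # antisymmetry under argument swap
    expect_identical(compute_ccg(b, a)$counts, rev(cc$counts))
  }
  expect_equal(sum(compute_ccg(numeric(0), c(1, 2))$counts), 0L)
})

test_that("a deterministic 3 ms shift concentrates all pairs at +3 ms", {
  a <- sort(runif(500, 0, 500))
  b <- a + 0.003
  cc <- compute_ccg(a, b)
  expect_gte(cc$counts[cc$lag_ms == 3], 500L)
  conn <- detect_connection(cc, convolution_null(cc))
  expect_identical(conn$pre, "a")
  expect_identical(conn$lag_ms, 3)
  expect_identical(conn$latency_ms, 3)
})

test_that("independent Poisson pairs produce flat CCGs at the coincidence rate", {
  set.seed(56)
  a <- sort(runif(1500, 0, 300))   # 5 Hz, 300 s
  b <- sort(runif(1500, 0, 300))
  cc <- compute_ccg(a, b)
  lambda <- 5 * 5 * 300 * 0.001    # r_a * r_b * T * bin = 7.5
  expect_true(all(abs(cc$counts - lambda) < 4 * sqrt(lambda)))
})

test_that("the convolution null matches Poisson-quantile oracles", {
  # flat CCG: the predictor reproduces the constant level in the interior
  flat <- structure(list(lag_ms = -50:50, counts = rep(20L, 101),
                         params = ccg_params()), class = "ccg")
  null <- convolution_null(flat)
  expect_equal(null$predictor[20:82], rep(20, 63), tolerance = 1e-9)
  # upper band at predictor 7.5, alpha 0.01: smallest k with CDF >= 0.99
  expect_identical(oracle_poisson_band(7.5, 0.01), 15)
  flat$counts <- rep(7L, 101)
  null2 <- convolution_null(flat)
  mid <- abs(flat$lag_ms) <= 10
  expect_equal(null2$upper[mid],
               oracle_poisson_band(null2$predictor[mid], 0.01))
  # a sharp peak does not predict itself (hollow centre)
  peaked <- flat
  peaked$counts <- rep(7L, 101); peaked$counts[51] <- 100L
  null3 <- convolution_null(peaked)
  expect_lt(null3$predictor[51], 20)
  expect_error(convolution_null(structure(list(lag_ms = -5:5,
                                               counts = rep(1L, 11),
                                               params = ccg_params()),
                                          class = "ccg")),
               "kernel wider")
})

test_that("lag-0-only significance is ambiguous and yields no connection", {
  cc <- structure(list(lag_ms = -50:50, counts = rep(7L, 101),
                       params = ccg_params()), class = "ccg")
  cc$counts[51] <- 60L                 # common-input-like zero-lag peak
  null <- convolution_null(cc)
  conn <- detect_connection(cc, null)
  expect_true(isTRUE(conn$ambiguous))
  expect_null(conn$pre)                # no directed connection is called
})

test_that("an injected synapse is detected at its latency and direction", {
  set.seed(57)
  spec <- network_spec(2, rate_hz = 10,
                       connections = data.frame(pre = 1, post = 2,
                                                latency_ms = 2, prob = 0.3),
                       burst_gain = 1)
  tr <- generate_network_spikes(spec, 300)
  cc <- compute_ccg(tr[["1"]], tr[["2"]])
  conn <- detect_connection(cc, convolution_null(cc))
  expect_identical(conn$pre, "a")
  expect_lte(abs(conn$latency_ms - 2), 1)
})

test_that("graphs collect edges, degrees and centre-to-centre distances", {
  set.seed(58)
  spec <- network_spec(3, rate_hz = 8,
                       connections = data.frame(pre = 1, post = 2,
                                                latency_ms = 3, prob = 0.4),
                       burst_gain = 1)
  tr <- generate_network_spikes(spec, 200)
  centers <- data.frame(unit = c("1", "2", "3"),
                        x = c(0, 300, 40), y = c(0, 0, 500))
  net <- build_graph(tr, centers)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$pre, "1")
  expect_identical(net$edges$post, "2")
  expect_equal(net$edges$distance_um, 300)
  expect_identical(net$degrees$degree, c(1L, 1L, 0L))
  # units below the spike floor are skipped, not tested
  tr$`3` <- tr$`3`[1:10]
  net2 <- build_graph(tr, centers)
  expect_identical(net2$untested, 2L)
})
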