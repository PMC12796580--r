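test_that("sweep normalization reproduces the 100-spikes/30-sweeps worked example", {
  fx <- build_fixture("psth_worked_example")
  events <- seq(0, by = 2000, length.out = fx$data$n_sweeps)
  # distribute 100 spikes over the first 10 sweeps, inside the 1-s window
  spikes <- sort(unlist(lapply(events[1:10], function(e)
    e + seq(50, 950, length.out = 10))))
  expect_equal(length(spikes), fx$data$n_spikes)
  rate <- window_rate(spikes, events, c(0, 1000))
  expect_equal(rate, fx$data$expected_rate)
  expect_equal(round(rate, 2), 3.33)
  p <- build_psth(spikes, events, window = c(0, 1000), bin_width = 2)
  expect_equal(sum(p$rate) * p$bin_width / 1000, rate * 1)
})

test_that("one spike per sweep at +10 ms fills exactly the [10,12) bin at 500 spikes/s", {
  events <- seq(1000, by = 2000, length.out = 30)
  spikes <- events + 10
  p <- build_psth(spikes, events, window = c(-200, 100), bin_width = 2)
  ctr <- psth_centers(p)
  expect_equal(p$rate[ctr == 11], 500)
  expect_equal(sum(p$rate[ctr != 11]), 0)
})

test_that("spikes on a bin edge fall into the right-hand bin", {
  events <- 1000
  p <- build_psth(1012, events, window = c(-200, 100), bin_width = 2)
  ctr <- psth_centers(p)
  expect_equal(p$rate[ctr == 13], 500)  # 1 spike / 1 sweep / 2 ms
  expect_equal(p$rate[ctr == 11], 0)
  # a spike exactly on the right window edge is excluded
  p2 <- build_psth(1100, events, window = c(-200, 100), bin_width = 2)
  expect_equal(sum(p2$counts), 0)
})

test_that("no spikes gives an all-zero PSTH; zero events is an error", {
  p <- build_psth(numeric(0), events = c(0, 1000), window = c(0, 100))
  expect_true(all(p$rate == 0))
  expect_error(build_psth(1:5, numeric(0), c(0, 100)), "zero events")
  expect_error(build_psth(1:5, c(0, 500), c(0, 100), bin_width = 3),
               "configuration error")
})

test_that("PSTH conserves total spike count and ignores sweep order", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      events <- sort(runif(20, 500, 50000))
      spikes <- sort(runif(400, 0, 52000))
      p <- build_psth(spikes, events, window = c(-100, 100), bin_width = 4)
      manual <- sum(vapply(events, function(e)
        sum(spikes >= e - 100 & spikes < e + 100), numeric(1)))
      expect_equal(sum(p$counts), manual)
      expect_equal(sum(p$rate) * p$bin_width / 1000 * p$n_sweeps / 1,
                   manual / 1000 * 1000, tolerance = 1e-12)
      p_shuf <- build_psth(spikes, sample(events), window = c(-100, 100),
                           bin_width = 4)
      expect_equal(p_shuf$rate, p$rate)
    }
  })
})

test_that("window_rate uses only filtered sweeps and errors on empty selection", {
  events <- c(1000, 3000, 5000, 7000)
  spikes <- c(1010, 1020, 3010, 5010, 5020, 5030)
  r_all <- window_rate(spikes, events, c(0, 50))
  expect_equal(r_all, 6 / 4 / 0.05)
  keep <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(window_rate(spikes, events, c(0, 50), keep), 5 / 2 / 0.05)
  expect_error(window_rate(spikes, events, c(0, 50), rep(FALSE, 4)),
               "empty selection")
})

test_that("window_rate recovers a 10 spikes/s unit within the exact Poisson interval", {
  proto <- protocol_config(n_sweeps_per_condition = 100, n_cycles = 1,
                           conditions = "puff_only", puff_rate = 2, seed = 77)
  u <- unit_spec("w", "S1", depth = 800, base_rate = 10, wer_amplitude = 0)
  s <- generate_session(proto, list(u), quiet_states())
  ev <- s$events$deflection_ms
  r <- window_rate(s$spikes$w, ev, c(-50, 0))
  lam <- 10 * 100 * 0.05          # expected total count over all windows
  n_obs <- r * 100 * 0.05
  expect_gte(n_obs, qpois(0.005, lam))
  expect_lte(n_obs, qpois(0.995, lam))
})

test_that("whisking-to-quiet PSTH baseline ratio recovers the configured multiplier", {
  proto <- protocol_config(n_sweeps_per_condition = 150, n_cycles = 1,
                           conditions = "puff_only", seed = 55)
  u <- unit_spec("m", "S1", depth = 800, base_rate = 5,
                 whisking_multiplier = 2)
  s <- generate_session(proto, list(u), state_config())
  lab <- assign_sweep_states(s$states_truth, s)
  ev <- s$events$deflection_ms
  r_q <- window_rate(s$spikes$m, ev, c(-200, 0), lab == "quiet")
  r_w <- window_rate(s$spikes$m, ev, c(-200, 0), lab == "whisking")
  expect_equal(r_w / r_q, 2, tolerance = 0.35)
})

test_that("threshold detection finds embedded spikes and rejects flat traces", {
  fs <- 20000
  withr::with_seed(12, {
    n <- fs * 5
    trace <- rnorm(n)
    at <- sort(sample(seq(1000, n - 1000), 50))
    at <- at[c(TRUE, diff(at) > 200)]
    while (length(at) < 50) {
      extra <- sample(seq(1000, n - 1000), 1)
      if (all(abs(extra - at) > 200)) at <- sort(c(at, extra))
    }
    # biphasic 8-SD events, wider than one sample so the band-pass keeps them
    for (a in at) {
      trace[a:(a + 10)] <- trace[a:(a + 10)] - 8 * exp(-(0:10) / 3)
    }
    det <- detect_spikes(trace, fs, threshold_sd = 4)
    found <- vapply(at / fs * 1000, function(t0)
      any(abs(det - t0) < 1), logical(1))
    expect_equal(sum(found), 50)
  })
  expect_warning(out <- detect_spikes(numeric(10000), 20000), "flat trace")
  expect_equal(length(out), 0)
})

test_that("false positives on pure noise match the Gaussian tail bound to an order of magnitude", {
  fs <- 20000
  withr::with_seed(13, trace <- rnorm(fs * 100))
  det <- detect_spikes(trace, fs, threshold_sd = 4)
  expected <- length(trace) * pnorm(-4)
  expect_gte(length(det), expected / 10)
  expect_lte(length(det), expected * 10)
})
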