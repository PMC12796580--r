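test_that("a flat PSTH has no onset; a clean step forces the printed onset", {
  expect_true(is.na(detect_response_onset(flat_psth(5))))

  fx <- build_fixture("onset_step")
  nbins <- as.integer(diff(fx$data$window_ms) / fx$data$bin_width_ms)
  rates <- rep(fx$data$baseline_rate, nbins)
  starts <- fx$data$window_ms[1] + fx$data$bin_width_ms * (0:(nbins - 1))
  step_bins <- which(starts >= fx$data$step_at_ms)[seq_len(fx$data$step_bins)]
  rates[step_bins] <- fx$data$step_rate
  p <- make_psth(rates, window = fx$data$window_ms,
                 bin_width = fx$data$bin_width_ms)
  expect_equal(detect_response_onset(p), fx$data$expected_onset_ms)
})

test_that("runs shorter than the minimum number of bins are not onsets", {
  rates <- rep(5, 150)
  rates[101:104] <- 50           # only 4 supra-threshold bins from 0 ms
  p <- make_psth(rates)
  expect_true(is.na(detect_response_onset(p)))
  rates[101:105] <- 50
  expect_equal(detect_response_onset(make_psth(rates)), 0)
})

test_that("the onset detector is translation-equivariant", {
  rates <- rep(2, 150)
  rates[106:120] <- 30           # step at +10 ms in the default window
  p <- make_psth(rates)
  expect_equal(detect_response_onset(p), 10)
  shift <- 20
  p_shift <- make_psth(rates, window = c(-200 + shift, 100 + shift))
  expect_equal(
    detect_response_onset(p_shift, baseline_window = c(-200 + shift, shift)),
    10 + shift)
})

test_that("noisy step PSTHs yield a median onset within one bin of the truth", {
  # reduced-size replicate check; the full 200-replicate version runs in
  # the acceptance suite
  proto <- protocol_config(n_sweeps_per_condition = 1500, n_cycles = 1,
                           conditions = "puff_only", puff_rate = 2, seed = 23)
  u <- unit_spec("step", "S1", depth = 800, base_rate = 2,
                 wer_amplitude = 78, wer_onset = 8, wer_peak = 38,
                 wer_shape = "boxcar")
  s <- generate_session(proto, list(u), quiet_states())
  ev <- s$events$deflection_ms
  groups <- split(seq_along(ev), rep(1:50, each = 30))
  onsets <- vapply(groups, function(idx) {
    p <- build_psth(s$spikes$step, ev[idx], c(-200, 100), 2)
    detect_response_onset(p)
  }, numeric(1))
  expect_lte(abs(median(onsets, na.rm = TRUE) - 8), 2)
})

test_that("biphasic window rates recover component structure and tile additively", {
  # analytic two-component PSTH evaluated from the rate model directly
  u <- unit_spec("v", "VPM", base_rate = 2, wer_amplitude = 100,
                 wer_onset = 5, wer_peak = 10, wer_decay = 8,
                 wer2 = list(onset = 41, amplitude = 50, decay = 20))
  ctr <- seq(-199, 99, by = 2)
  rate <- 2 + 100 * wer_kernel(ctr, 5, 10, 8) +
    50 * wer_kernel(ctr, 41, 45, 20)
  p <- make_psth(rate)
  bi <- split_biphasic(p, baseline_subtract = TRUE)
  # oracle: mean baseline-corrected rate = amplitude x kernel mean over bins
  sel1 <- ctr >= 5 & ctr <= 40
  sel2 <- ctr >= 41 & ctr <= 100
  exp1 <- mean(100 * wer_kernel(ctr[sel1], 5, 10, 8) +
                 50 * wer_kernel(ctr[sel1], 41, 45, 20))
  exp2 <- mean(100 * wer_kernel(ctr[sel2], 5, 10, 8) +
                 50 * wer_kernel(ctr[sel2], 41, 45, 20))
  expect_equal(bi$wer1_rate, exp1, tolerance = 1e-12)
  expect_equal(bi$wer2_rate, exp2, tolerance = 1e-12)

  # absent second component: late window sits at baseline
  rate0 <- 2 + 100 * wer_kernel(ctr, 5, 10, 8)
  bi0 <- split_biphasic(make_psth(rate0), late = c(61, 100))
  expect_equal(bi0$wer2_rate, 2, tolerance = 0.1)

  # window rates tile: weighted mean over adjacent windows = full window
  full <- psth_window_rate(p, c(5, 100))
  n1 <- sum(sel1); n2 <- sum(sel2)
  expect_equal((n1 * bi$wer1_rate + n2 * bi$wer2_rate) / (n1 + n2) +
                 0, full - 2, tolerance = 1e-12)
  expect_error(split_biphasic(p, early = c(5, 50), late = c(41, 100)),
               "configuration error")
})

test_that("an early window empty of spikes yields zero rate", {
  rates <- rep(0, 150)
  rates[146:150] <- 10           # activity only from +90 ms
  p <- make_psth(rates)
  expect_equal(split_biphasic(p)$wer1_rate, 0)
})

test_that("response slope is exact on a linear ramp and zero on a flat segment", {
  ctr <- seq(-199, 99, by = 2)
  rate <- ifelse(ctr >= 0 & ctr <= 20, 2 * pmax(ctr, 0), 0)
  p <- make_psth(rate)
  expect_equal(response_slope(p, 0, 20), 2, tolerance = 1e-12)
  expect_equal(response_slope(flat_psth(7), 0, 40), 0)
  expect_error(response_slope(p, 10, 10), "input error")
  expect_error(response_slope(make_psth(rate), 18.5, 19),
               "degenerate interval")
})

test_that("slope estimates on noisy ramps are unbiased within 5%", {
  ctr <- seq(-199, 99, by = 2)
  truth <- 2
  base <- ifelse(ctr >= 0 & ctr <= 40, truth * pmax(ctr, 0), 0)
  withr::with_seed(31, {
    slopes <- vapply(1:500, function(i) {
      p <- make_psth(base + rnorm(length(base), 0, 5))
      response_slope(p, 0, 40)
    }, numeric(1))
  })
  expect_lt(abs(mean(slopes) - truth) / truth, 0.05)
})

test_that("peak finding takes the earliest maximum within the evoked window", {
  rates <- rep(0, 150)
  rates[c(110, 120)] <- 40       # tie: two equal maxima
  p <- make_psth(rates)
  pk <- find_response_peak(p)
  expect_equal(pk$rate, 40)
  expect_equal(pk$time, psth_centers(p)[110])
})

test_that("condition deltas subtract window rates and validate binning", {
  fx <- build_fixture("delta_example")
  p_ctrl <- flat_psth(fx$data$control_rate)
  p_opto <- flat_psth(fx$data$opto_rate)
  expect_equal(condition_delta(p_ctrl, p_opto, c(-50, 0)),
               fx$data$expected_delta, tolerance = 1e-12)
  expect_equal(condition_delta(p_ctrl, p_ctrl, c(-50, 0)), 0)
  p_bad <- flat_psth(fx$data$opto_rate, bin_width = 4)
  expect_error(condition_delta(p_ctrl, p_bad, c(-50, 0)), "mismatched")
})

test_that("simulated 50% suppression of a 10 spikes/s unit gives a delta near 5", {
  proto <- protocol_config(n_sweeps_per_condition = 300, n_cycles = 1,
                           conditions = c("puff_only", "combined"),
                           puff_rate = 2, seed = 47)
  u <- unit_spec("d", "POm", base_rate = 10, opto_suppression = 0.5,
                 opto_latency = 0)
  s <- generate_session(proto, list(u), quiet_states())
  ev <- s$events
  ctrl <- ev$deflection_ms[ev$condition == "puff_only"]
  opto <- ev$deflection_ms[ev$condition == "combined"]
  delta <- window_rate(s$spikes$d, ctrl, c(-50, 0)) -
    window_rate(s$spikes$d, opto, c(-50, 0))
  # 99% CI half-width for the difference of two Poisson rate estimates
  se <- sqrt(10 / (300 * 0.05) + 5 / (300 * 0.05))
  expect_lt(abs(delta - 5), 2.58 * se)
})
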