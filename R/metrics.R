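#' Detect the onset of an evoked response
#'
#' Threshold rule on the sweep-averaged PSTH: the baseline mean plus
#' `k_sd` baseline SDs (computed over the 2-ms bins of the 200 ms
#' preceding the stimulus) must be strictly exceeded for at least
#' `min_consecutive` consecutive post-stimulus bins; the onset is the
#' left edge of the first bin of the first such run. By construction the
#' detector never fires during the baseline window.
#'
#' @param p a `whisk_psth` aligned to the stimulus
#' @param baseline_window baseline interval, ms (default `c(-200, 0)`)
#' @param k_sd SD multiplier (default 2)
#' @param min_consecutive minimum run length in bins (default 5)
#' @return onset time in ms, or `NA_real_` when no run qualifies
#' @export
detect_response_onset <- function(p, baseline_window = c(-200, 0),
                                  k_sd = 2, min_consecutive = 5L) {
  edges <- p$bin_edges
  starts <- head(edges, -1); ends <- tail(edges, -1)
  base_idx <- starts >= baseline_window[1] & ends <= baseline_window[2]
  if (sum(base_idx) < 2L)
    stop("input error: fewer than 2 baseline bins; baseline SD undefined")
  thr <- mean(p$rate[base_idx]) + k_sd * sd(p$rate[base_idx])
  post <- which(starts >= 0)
  if (!length(post)) return(NA_real_)
  supra <- p$rate[post] > thr
  r <- rle(supra)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_consecutive)
  if (!length(hit)) return(NA_real_)
  starts[post[run_start[hit[1]]]]
}

#' Locate the peak of the evoked response
#'
#' Maximum PSTH bin between `window[1]` and `window[2]`; ties resolve to
#' the earliest bin. Returns the bin-center time and rate.
#'
#' @param p a `whisk_psth`
#' @param window search interval, ms (default `c(0, 100)`)
#' @return `list(time, rate)` - bin center (ms) and rate (spikes/s)
#' @export
find_response_peak <- function(p, window = c(0, 100)) {
  ctr <- psth_centers(p)
  sel <- which(ctr >= window[1] & ctr <= window[2])
  if (!length(sel)) stop("input error: peak window contains no bins")
  i <- sel[which.max(p$rate[sel])]
  list(time = ctr[i], rate = p$rate[i])
}

#' Split an evoked response into early and late components
#'
#' Mean rates over an early and a late post-stimulus window (defaults
#' 5-40 ms and 41-100 ms, the biphasic split typical of first-order
#' thalamic responses), optionally baseline-subtracted. Bins are
#' selected by center, so adjacent windows sharing an edge do not double
#' count.
#'
#' @param p a `whisk_psth` aligned to the stimulus
#' @param early,late window intervals, ms; must not overlap
#' @param baseline_subtract subtract the baseline-window mean rate
#' @param baseline_window baseline interval, ms
#' @return `list(wer1_rate, wer2_rate)` in spikes/s
#' @export
split_biphasic <- function(p, early = c(5, 40), late = c(41, 100),
                           baseline_subtract = FALSE,
                           baseline_window = c(-200, 0)) {
  if (early[2] > late[1])
    stop("configuration error: early and late windows overlap")
  w1 <- psth_window_rate(p, early)
  w2 <- psth_window_rate(p, late)
  if (baseline_subtract) {
    b <- psth_window_rate(p, baseline_window)
    w1 <- w1 - b
    w2 <- w2 - b
  }
  list(wer1_rate = w1, wer2_rate = w2)
}

#' Slope of the evoked response from onset to peak
#'
#' Ordinary least-squares slope of PSTH bin rate against bin-center time
#' over `[onset, peak_time]`, in spikes/s per ms.
#'
#' @param p a `whisk_psth`
#' @param onset response onset, ms (e.g. from [detect_response_onset()])
#' @param peak_time time of the response maximum, ms
#' @return OLS slope, spikes/s per ms
#' @export
response_slope <- function(p, onset, peak_time) {
  if (is.na(onset) || onset >= peak_time)
    stop("input error: need onset < peak_time")
  ctr <- psth_centers(p)
  sel <- ctr >= onset & ctr <= peak_time
  if (sum(sel) < 2L)
    stop("degenerate interval: onset and peak fall in the same bin")
  x <- ctr[sel]; y <- p$rate[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Control-minus-photoinactivation rate difference
#'
#' Window rate of the control PSTH minus window rate of the
#' photoinactivation PSTH, for one unit; both PSTHs must share
#' alignment, binning and state label.
#'
#' @param p_ctrl,p_opto `whisk_psth` objects under control and light
#' @param window interval, ms
#' @return delta rate, spikes/s (positive = suppression)
#' @export
condition_delta <- function(p_ctrl, p_opto, window) {
  if (!isTRUE(all.equal(p_ctrl$bin_edges, p_opto$bin_edges)) ||
      p_ctrl$alignment != p_opto$alignment)
    stop("input error: PSTHs have mismatched binning or alignment")
  psth_window_rate(p_ctrl, window) - psth_window_rate(p_opto, window)
}

#' Full response-metric set for one unit and condition
#'
#' Convenience wrapper that computes onset, peak, slope, and the
#' biphasic window rates from one stimulus-aligned PSTH.
#'
#' @param p a `whisk_psth` aligned to the deflection
#' @param baseline_window baseline interval, ms
#' @param evoked_window peak-search interval, ms
#' @param early,late biphasic split windows, ms
#' @return `list(onset_latency, peak_rate, peak_time, slope, wer1_rate,
#'   wer2_rate)`; slope is `NA` when no onset is found or the onset bin
#'   equals the peak bin
#' @export
response_metrics <- function(p, baseline_window = c(-200, 0),
                             evoked_window = c(0, 100),
                             early = c(5, 40), late = c(41, 100)) {
  onset <- detect_response_onset(p, baseline_window)
  peak <- find_response_peak(p, evoked_window)
  slope <- if (!is.na(onset) && onset < peak$time) {
    tryCatch(response_slope(p, onset, peak$time), error = function(e) NA_real_)
  } else NA_real_
  bi <- split_biphasic(p, early, late)
  list(onset_latency = onset, peak_rate = peak$rate, peak_time = peak$time,
       slope = slope, wer1_rate = bi$wer1_rate, wer2_rate = bi$wer2_rate)
}
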