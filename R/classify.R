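#' Opto-tag classification from a light-aligned PSTH
#'
#' A unit belongs to the photoinactivated (transfected) population if
#' its averaged spontaneous activity drops within the first 5.5 ms after
#' light onset. Baseline mean and SD are computed over the 2-ms bins of
#' the sweep-averaged PSTH in the 200 ms preceding the pulse. Units with
#' baseline below `rate_floor` (default 1 spike/s) are unclassifiable.
#'
#' The default `rule = "corrected"` tags a unit when its mean rate over
#' the tag window is at most `max(0, mu - k_sd * sigma)`; when
#' `mu - k_sd * sigma` is negative the criterion falls back to requiring
#' zero tag-window activity together with a full-pulse rate below the
#' baseline mean. `rule = "literal"` applies the criterion as sometimes
#' printed (below `mu + k_sd * sigma`), kept selectable so the
#' discrepancy between the two readings is auditable; it is not the
#' default because any unit whose rate merely fails to increase would
#' satisfy it.
#'
#' @param psth_light a `whisk_psth` aligned to light onset at 2-ms bins,
#'   covering both windows
#' @param baseline_window baseline interval, ms (default `c(-200, 0)`)
#' @param tag_window tag interval, ms (default `c(0, 5.5)`; bins
#'   overlapping the window are used)
#' @param k_sd SD multiplier (default 2)
#' @param rate_floor minimum classifiable baseline rate, spikes/s
#' @param pulse_window full light-pulse interval, ms (for the fallback)
#' @param rule `"corrected"` (mu - k*SD) or `"literal"` (mu + k*SD)
#' @return one of `"tagged"`, `"not_tagged"`, `"unclassifiable"`
#' @export
classify_optotag <- function(psth_light,
                             baseline_window = c(-200, 0),
                             tag_window = c(0, 5.5),
                             k_sd = 2,
                             rate_floor = 1,
                             pulse_window = c(0, 70),
                             rule = c("corrected", "literal")) {
  rule <- match.arg(rule)
  if (!inherits(psth_light, "whisk_psth"))
    stop("input error: psth_light must be a whisk_psth (missing light events?)")
  edges <- psth_light$bin_edges
  starts <- head(edges, -1); ends <- tail(edges, -1)
  base_idx <- starts >= baseline_window[1] & ends <= baseline_window[2]
  if (sum(base_idx) < 2L)
    stop("input error: PSTH does not cover the baseline window")
  tag_idx <- starts < tag_window[2] & ends > tag_window[1]
  if (!any(tag_idx))
    stop("input error: PSTH does not cover the tag window")
  mu <- mean(psth_light$rate[base_idx])
  sigma <- sd(psth_light$rate[base_idx])
  if (mu < rate_floor) return("unclassifiable")
  tag_rate <- mean(psth_light$rate[tag_idx])
  if (rule == "literal") {
    return(if (tag_rate < mu + k_sd * sigma) "tagged" else "not_tagged")
  }
  thr <- mu - k_sd * sigma
  if (thr >= 0) {
    if (tag_rate <= thr) "tagged" else "not_tagged"
  } else {
    pulse_idx <- starts < pulse_window[2] & ends > pulse_window[1]
    pulse_rate <- mean(psth_light$rate[pulse_idx])
    if (tag_rate == 0 && pulse_rate < mu) "tagged" else "not_tagged"
  }
}

#' Fast-spiking interneuron classification from waveform features
#'
#' Pure conjunction of three strict criteria: peak amplitude asymmetry
#' greater than 0.15, trough-to-peak latency below 0.3 ms, and spike
#' half-width below 0.2 ms. All three must hold.
#'
#' @param w a [waveform_features()] object (all features required)
#' @return logical: `TRUE` for a putative interneuron
#' @export
classify_interneuron <- function(w) {
  if (!inherits(w, "waveform_features"))
    stop("input error: w must be a waveform_features object")
  feats <- c(w$peak_amplitude_asymmetry, w$trough_to_peak, w$half_width)
  if (any(is.na(feats))) stop("input error: missing waveform feature")
  w$peak_amplitude_asymmetry > 0.15 &&
    w$trough_to_peak < 0.3 &&
    w$half_width < 0.2
}

#' Cortical layer from recording depth
#'
#' Half-open depth borders: L2/3 65-319 um, L4 320-539 um, L5 540-774
#' um, L6 deeper than 775 um; depths above 65 um fall outside the
#' layered cortex.
#'
#' @param depth recording depth, micrometers (>= 0)
#' @return one of `"L2/3"`, `"L4"`, `"L5"`, `"L6"`, `"outside"`
#' @export
assign_layer <- function(depth) {
  if (any(is.na(depth)) || any(depth < 0))
    stop("input error: depth must be non-negative")
  cut_points <- c(0, 65, 320, 540, 775, Inf)
  labels <- c("outside", "L2/3", "L4", "L5", "L6")
  labels[findInterval(depth, cut_points)]
}
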