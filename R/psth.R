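#' Detect spikes in a raw voltage trace
#'
#' Zero-phase 4th-order Butterworth band-pass (default 300-3000 Hz),
#' then negative-going threshold crossings at `threshold_sd` standard
#' deviations of the filtered trace (the classical 4-SD criterion).
#' Crossings closer than `refractory_ms` are merged into one event.
#'
#' @param raw numeric voltage trace
#' @param fs sampling rate, Hz
#' @param band band-pass edges, Hz
#' @param threshold_sd threshold in SD units (default 4)
#' @param refractory_ms merge window for consecutive crossings, ms
#' @return spike times, ms from trace start
#' @export
detect_spikes <- function(raw, fs, band = c(300, 3000),
                          threshold_sd = 4, refractory_ms = 1) {
  if (fs < 2 * band[2])
    stop("input error: sample rate must be at least twice the band upper edge")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, raw)
  s <- sd(filt)
  if (s == 0) {
    warning("flat trace (SD = 0): no spikes detected")
    return(numeric(0))
  }
  thr <- -threshold_sd * s
  below <- filt < thr
  onsets <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(onsets)) return(numeric(0))
  times <- (onsets - 1) / fs * 1000
  keep <- c(TRUE, diff(times) > refractory_ms)
  times[keep]
}

#' Build a per-sweep-normalized peristimulus time histogram
#'
#' Spikes are aligned to each event, binned into half-open `[t, t+bin)`
#' bins, summed over sweeps, and normalized by the number of sweeps and
#' the bin width, giving spikes/s per bin. The normalization follows the
#' sweep convention: 100 spikes collected over 30 sweeps in a 1-s window
#' yield 100/30 = 3.33 spikes/s.
#'
#' @param spikes sorted spike times, ms (one unit)
#' @param events alignment times, ms (one per sweep)
#' @param window analysis window relative to the event, ms
#' @param bin_width bin width, ms (default 2; must divide the window)
#' @param alignment metadata: `"deflection"` or `"light_on"`
#' @param state_label metadata: brain-state label of the sweeps
#' @return an object of class `whisk_psth`: `bin_edges` (length
#'   nbins + 1), `rate` (spikes/s), `n_sweeps`, `alignment`,
#'   `state_label`, `bin_width`
#' @export
build_psth <- function(spikes, events, window = c(-200, 100),
                       bin_width = 2,
                       alignment = c("deflection", "light_on"),
                       state_label = NA_character_) {
  alignment <- match.arg(alignment)
  if (!length(events)) stop("input error: zero events")
  span <- diff(window)
  nbins <- span / bin_width
  if (abs(nbins - round(nbins)) > 1e-9)
    stop("configuration error: bin_width must divide the window length")
  nbins <- as.integer(round(nbins))
  spikes <- sort(spikes)
  counts <- integer(nbins)
  for (ev in events) {
    rel <- .slice_in(spikes, ev + window[1], ev + window[2]) - ev
    if (length(rel)) {
      idx <- floor((rel - window[1]) / bin_width) + 1L
      idx <- idx[idx >= 1L & idx <= nbins]
      counts <- counts + tabulate(idx, nbins)
    }
  }
  n_sweeps <- length(events)
  structure(list(
    bin_edges = window[1] + bin_width * (0:nbins),
    rate = counts / n_sweeps / (bin_width / 1000),
    counts = counts,
    n_sweeps = n_sweeps,
    bin_width = bin_width,
    window = window,
    alignment = alignment,
    state_label = state_label
  ), class = "whisk_psth")
}

#' Bin centers of a PSTH
#' @param p a `whisk_psth`
#' @return numeric vector of bin-center times, ms
#' @export
psth_centers <- function(p) {
  (head(p$bin_edges, -1) + tail(p$bin_edges, -1)) / 2
}

#' Mean rate of a PSTH over a sub-window
#'
#' Bins are selected by their centers, so a boundary placed on a bin
#' edge splits cleanly between adjacent windows.
#'
#' @param p a `whisk_psth`
#' @param window time interval, ms, relative to the alignment event
#' @return mean rate over the selected bins, spikes/s
#' @export
psth_window_rate <- function(p, window) {
  ctr <- psth_centers(p)
  sel <- ctr >= window[1] & ctr <= window[2]
  if (!any(sel)) stop("input error: window contains no PSTH bins")
  mean(p$rate[sel])
}

#' Window firing rate over selected sweeps
#'
#' Rate in a fixed window around each event, computed only over sweeps
#' passing `state_filter`; the denominator is the number of included
#' sweeps times the window duration. Used for, e.g., the baseline window
#' from light onset to the start of the whisker deflection.
#'
#' @param spikes sorted spike times, ms
#' @param events alignment times, ms (one per sweep)
#' @param window interval relative to the event, ms (half-open)
#' @param state_filter optional logical vector (or labels plus `keep`)
#'   selecting sweeps; `NULL` keeps all
#' @return rate in spikes/s
#' @export
window_rate <- function(spikes, events, window, state_filter = NULL) {
  if (!is.null(state_filter)) {
    stopifnot(length(state_filter) == length(events))
    events <- events[state_filter]
  }
  if (!length(events))
    stop("empty selection: no sweeps pass the state filter")
  spikes <- sort(spikes)
  total <- 0L
  for (ev in events) {
    total <- total + .count_in(spikes, ev + window[1], ev + window[2])
  }
  total / length(events) / (diff(window) / 1000)
}

#' @export
print.whisk_psth <- function(x, ...) {
  cat(sprintf("whisk_psth: [%g, %g] ms @ %g ms bins, %d sweeps, align %s%s\n",
              x$window[1], x$window[2], x$bin_width, x$n_sweeps, x$alignment,
              if (!is.na(x$state_label)) paste0(", state ", x$state_label) else ""))
  invisible(x)
}

#' Write a PSTH to CSV with a JSON metadata sidecar
#'
#' @param p a `whisk_psth`
#' @param path CSV output path; metadata goes to `<path>.json`
#' @return `path`, invisibly
#' @export
write_psth_csv <- function(p, path) {
  df <- data.frame(bin_start_ms = head(p$bin_edges, -1),
                   bin_end_ms = tail(p$bin_edges, -1),
                   rate_spikes_per_s = p$rate)
  write.csv(df, path, row.names = FALSE)
  meta <- list(n_sweeps = p$n_sweeps, bin_width_ms = p$bin_width,
               window_ms = p$window, alignment = p$alignment,
               state_label = p$state_label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
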