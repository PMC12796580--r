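#' Sliding-window Welch spectrogram of an LFP trace
#'
#' Splits the trace into sliding analysis windows and estimates each
#' window's power spectral density by Welch's method: the window is cut
#' into `n_segments` half-overlapping Hamming-tapered segments whose
#' periodograms are averaged. Power is stored on a log10 scale, the
#' convention used when states are read off an LFP spectrogram by eye.
#'
#' @param lfp an `lfp_trace` (`list(samples, fs)`) as produced by
#'   [generate_lfp()], or any list with those fields
#' @param window_length analysis-window length, ms (default 1000)
#' @param overlap_fraction overlap between consecutive analysis windows
#'   (default 0.5)
#' @param n_segments Welch segments per window (default 4)
#' @return an object of class `whisk_spectrogram`: `window_times`
#'   (centers, ms), `frequencies` (Hz), `psd` (log10 power, windows x
#'   frequencies), plus window metadata
#' @export
compute_spectrogram <- function(lfp, window_length = 1000,
                                overlap_fraction = 0.5,
                                n_segments = 4L) {
  fs <- lfp$fs
  x <- lfp$samples
  win_n <- round(window_length / 1000 * fs)
  if (win_n > length(x))
    stop("input error: window longer than the LFP trace")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("configuration error: overlap_fraction must be in [0, 1)")
  step_n <- max(1L, round(win_n * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - win_n + 1L, by = step_n)

  # Welch segmentation within one analysis window
  seg_n <- max(8L, floor(2 * win_n / (n_segments + 1)))
  seg_step <- max(1L, floor(seg_n / 2))
  taper <- signal::hamming(seg_n)
  taper_norm <- sum(taper^2)
  nf <- floor(seg_n / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / seg_n

  psd <- matrix(0, nrow = length(starts), ncol = nf)
  for (i in seq_along(starts)) {
    w <- x[starts[i]:(starts[i] + win_n - 1L)]
    seg_starts <- seq(1L, win_n - seg_n + 1L, by = seg_step)
    acc <- numeric(nf)
    for (s0 in seg_starts) {
      seg <- w[s0:(s0 + seg_n - 1L)]
      seg <- (seg - mean(seg)) * taper
      sp <- abs(fft(seg))^2 / (taper_norm * fs)
      half <- sp[seq_len(nf)]
      # fold two-sided spectrum onto [0, Nyquist]
      if (seg_n %% 2 == 0) {
        half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
      } else {
        half[2:nf] <- 2 * half[2:nf]
      }
      acc <- acc + half
    }
    psd[i, ] <- acc / length(seg_starts)
  }
  psd_log <- log10(pmax(psd, .Machine$double.xmin))
  structure(list(
    window_times = (starts - 1L + win_n / 2) / fs * 1000,
    frequencies = freqs,
    psd = psd_log,
    window_length = window_length,
    overlap_fraction = overlap_fraction,
    step_ms = step_n / fs * 1000,
    duration_ms = length(x) / fs * 1000
  ), class = "whisk_spectrogram")
}

.band_power <- function(psd_lin_row, freqs, bands) {
  # integrate linear power over the union of the bands (overlapping band
  # edges are merged so shared frequencies are not double counted)
  bands <- bands[order(vapply(bands, `[`, numeric(1), 1))]
  merged <- list()
  for (b in bands) {
    if (length(merged) && b[1] <= merged[[length(merged)]][2]) {
      merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], b[2])
    } else {
      merged[[length(merged) + 1L]] <- b
    }
  }
  total <- 0
  for (b in merged) {
    sel <- freqs >= b[1] & freqs <= b[2]
    total <- total + sum(psd_lin_row[sel])
  }
  total
}

#' Classify brain state from a spectrogram
#'
#' For each analysis window the ratio of linear power integrated over
#' the active bands (union, so the overlapping 25-30 Hz region is not
#' double counted) to power in the quiet band is computed. Windows with
#' ratio above `ratio_threshold` are labeled whisking, below
#' `1/ratio_threshold` quiet, and anything in between - including an
#' exact tie with the threshold - is excluded, mirroring the removal of
#' ambiguous "active non-whisking" episodes from analysis. Consecutive
#' same-label windows are merged and episodes shorter than `min_episode`
#' are relabeled excluded.
#'
#' @param spec a `whisk_spectrogram`
#' @param quiet_band quiet-state band, Hz
#' @param active_bands list of active-state bands, Hz
#' @param ratio_threshold decision ratio (default 1.5)
#' @param min_episode minimum episode duration, ms (default 500)
#' @return a [state_intervals()] table with provenance `"classified"`
#' @export
classify_states <- function(spec,
                            quiet_band = c(4, 12),
                            active_bands = list(c(13, 30), c(25, 60)),
                            ratio_threshold = 1.5,
                            min_episode = 500) {
  if (!inherits(spec, "whisk_spectrogram") || !nrow(spec$psd))
    stop("input error: empty spectrogram")
  psd_lin <- 10^spec$psd
  n <- nrow(psd_lin)
  labels <- character(n)
  for (i in seq_len(n)) {
    pq <- .band_power(psd_lin[i, ], spec$frequencies, list(quiet_band))
    pa <- .band_power(psd_lin[i, ], spec$frequencies, active_bands)
    ratio <- if (pq > 0) pa / pq else Inf
    labels[i] <- if (ratio > ratio_threshold) "whisking"
    else if (ratio < 1 / ratio_threshold) "quiet"
    else "excluded"
  }
  # each window owns a step-wide segment centered on the window center;
  # the first and last windows absorb the trace edges
  half_step <- spec$step_ms / 2
  seg_start <- pmax(0, spec$window_times - half_step)
  seg_end <- pmin(spec$duration_ms, spec$window_times + half_step)
  seg_start[1] <- 0
  seg_end[n] <- spec$duration_ms
  # close inter-segment gaps (rounding) by extending to the next start
  if (n > 1L) seg_end[-n] <- seg_start[-1]

  # merge consecutive same-label segments
  runs <- rle(labels)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1L
  st <- seg_start[starts_idx]
  en <- seg_end[ends_idx]
  lab <- runs$values
  # short episodes are too brief to represent a brain state -> excluded
  lab[en - st < min_episode] <- "excluded"
  # re-merge after relabeling
  runs2 <- rle(lab)
  e2 <- cumsum(runs2$lengths)
  s2 <- e2 - runs2$lengths + 1L
  state_intervals(st[s2], en[e2], runs2$values, provenance = "classified")
}

#' Assign a brain-state label to each sweep
#'
#' A sweep is labeled quiet or whisking only if a single classified (or
#' ground-truth) state interval with that label covers its entire
#' analysis window; sweeps straddling a state transition, or touching
#' excluded time, are excluded (purity rule).
#'
#' @param states a [state_intervals()] table
#' @param session a `whisk_session`
#' @param analysis_window window relative to the deflection-at-whisker
#'   time, ms (default `c(-200, 100)`)
#' @return character vector of per-sweep labels
#'   (`"quiet"`/`"whisking"`/`"excluded"`), one per event-log row
#' @export
assign_sweep_states <- function(states, session,
                                analysis_window = c(-200, 100)) {
  ev <- session$events
  lo <- ev$deflection_ms + analysis_window[1]
  hi <- ev$deflection_ms + analysis_window[2]
  if (any(lo < 0) || any(hi > session$duration_ms))
    stop("input error: analysis window outside the session")
  out <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    idx <- findInterval(lo[i], states$start_ms)
    if (idx >= 1L && states$end_ms[idx] >= hi[i] &&
        states$start_ms[idx] <= lo[i] &&
        states$label[idx] != "excluded") {
      out[i] <- states$label[idx]
    } else {
      out[i] <- "excluded"
    }
  }
  out
}

#' Agreement between two state segmentations
#'
#' Compares a classified segmentation against ground truth on a common
#' time grid. Because the classifier deliberately excludes ambiguous
#' time (the removal rule for episodes that represent no clear brain
#' state), accuracy is reported over the labeled (non-excluded) time;
#' the labeled fraction itself is reported alongside.
#'
#' @param truth,classified [state_intervals()] tables
#' @param resolution_ms evaluation grid step (default 10 ms)
#' @return list with `accuracy_labeled` (agreement over time the
#'   classifier labels), `labeled_fraction`, and `accuracy_total`
#'   (agreement over all time, exclusions counting as mismatch)
#' @export
state_agreement <- function(truth, classified, resolution_ms = 10) {
  t_end <- min(max(truth$end_ms), max(classified$end_ms))
  grid <- seq(resolution_ms / 2, t_end, by = resolution_ms)
  lt <- .interval_label_at(truth, grid)
  lc <- .interval_label_at(classified, grid)
  ok <- !is.na(lt) & !is.na(lc)
  lt <- lt[ok]; lc <- lc[ok]
  labeled <- lc != "excluded"
  list(
    accuracy_labeled = if (any(labeled)) mean(lt[labeled] == lc[labeled]) else NA_real_,
    labeled_fraction = mean(labeled),
    accuracy_total = mean(lt == lc)
  )
}
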