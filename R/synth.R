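#' Whisker-evoked response kernel
#'
#' Evaluates the unit-amplitude evoked-rate kernel at times `t` (ms)
#' relative to the deflection reaching the whiskers. The `"alpha"` shape
#' rises linearly from `onset` to `peak` and decays exponentially with
#' time constant `decay` after the peak; `"boxcar"` is constant 1 on
#' `[onset, peak]`. Both are exactly integrable (see
#' [wer_kernel_integral()]), which the simulation oracles rely on.
#'
#' @param t times relative to deflection, ms
#' @param onset,peak,decay shape parameters, ms
#' @param shape `"alpha"` or `"boxcar"`
#' @return kernel values in `[0, 1]`
#' @export
wer_kernel <- function(t, onset, peak, decay, shape = c("alpha", "boxcar")) {
  shape <- match.arg(shape)
  k <- numeric(length(t))
  if (shape == "boxcar") {
    k[t >= onset & t <= peak] <- 1
    return(k)
  }
  rise <- t >= onset & t < peak
  fall <- t >= peak
  k[rise] <- (t[rise] - onset) / (peak - onset)
  k[fall] <- exp(-(t[fall] - peak) / decay)
  k
}

#' Exact integral of the evoked-rate kernel
#'
#' @inheritParams wer_kernel
#' @param upper upper integration limit, ms (from deflection)
#' @return integral of the unit-amplitude kernel over `[0, upper]`, in ms
#' @export
wer_kernel_integral <- function(onset, peak, decay,
                                shape = c("alpha", "boxcar"),
                                upper = Inf) {
  shape <- match.arg(shape)
  if (upper <= onset) return(0)
  if (shape == "boxcar") return(min(upper, peak) - onset)
  if (upper <= peak) return(0.5 * (upper - onset)^2 / (peak - onset))
  0.5 * (peak - onset) + decay * (1 - exp(-(upper - peak) / decay))
}

.kernel_support_end <- function(spec) {
  end1 <- if (spec$wer_amplitude > 0) {
    if (spec$wer_shape == "boxcar") spec$wer_peak
    else spec$wer_peak + 8 * spec$wer_decay
  } else 0
  end2 <- if (!is.null(spec$wer2)) spec$wer2$onset + .wer2_rise + 8 * spec$wer2$decay else 0
  max(end1, end2)
}

# fixed rise time of the late (second) WER component, ms
.wer2_rise <- 4

.build_event_log <- function(protocol) {
  interval_ms <- 1000 / protocol$puff_rate
  rows <- list()
  k <- 0L
  for (cyc in seq_len(protocol$n_cycles)) {
    order_cond <- sample(protocol$conditions)
    for (cond in order_cond) {
      for (s in seq_len(protocol$n_sweeps_per_condition)) {
        k <- k + 1L
        trigger <- (k - 1L) * interval_ms + 500
        deflection <- trigger + protocol$air_delay
        has_light <- cond %in% c("opto_only", "combined")
        has_puff <- cond %in% c("puff_only", "combined")
        light_on <- if (has_light) deflection - protocol$light_lead else NA_real_
        light_off <- if (has_light) light_on + protocol$light_duration else NA_real_
        rows[[k]] <- data.frame(
          sweep_id = k, cycle = cyc, condition = cond,
          trigger_ms = trigger, deflection_ms = deflection,
          light_on_ms = light_on, light_off_ms = light_off,
          has_puff = has_puff, has_light = has_light,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.generate_state_truth <- function(states, duration_ms) {
  if (states$whisk_mean_ms <= 0) {
    return(state_intervals(0, duration_ms, "quiet", provenance = "truth"))
  }
  starts <- numeric(0); ends <- numeric(0); labels <- character(0)
  t <- 0
  lab <- "quiet"
  while (t < duration_ms) {
    mu <- if (lab == "quiet") states$quiet_mean_ms else states$whisk_mean_ms
    dur <- max(states$min_bout, rexp(1, 1 / mu))
    e <- min(t + dur, duration_ms)
    starts <- c(starts, t); ends <- c(ends, e); labels <- c(labels, lab)
    t <- e
    lab <- if (lab == "quiet") "whisking" else "quiet"
  }
  state_intervals(starts, ends, labels, provenance = "truth")
}

.interval_label_at <- function(intervals, t) {
  idx <- findInterval(t, intervals$start_ms)
  lab <- rep(NA_character_, length(t))
  ok <- idx >= 1L
  lab[ok] <- ifelse(t[ok] < intervals$end_ms[idx[ok]],
                    intervals$label[idx[ok]], NA_character_)
  lab
}

#' Instantaneous firing rate of a unit specification
#'
#' Evaluates the rate model of [unit_spec()] on a session timeline:
#' baseline modulated by whisking state and by photoinactivation, plus
#' additive evoked kernels at the deflections of puff sweeps.
#'
#' @param t times, ms (session clock)
#' @param spec a [unit_spec()]
#' @param session a session (or a list with `events` and `states_truth`)
#' @return rate in spikes/s at each `t`; never negative
#' @export
unit_rate <- function(t, spec, session) {
  events <- session$events
  truth <- session$states_truth
  r <- rep(spec$base_rate, length(t))
  if (spec$whisking_multiplier != 1) {
    lab <- .interval_label_at(truth, t)
    r[!is.na(lab) & lab == "whisking"] <- spec$base_rate * spec$whisking_multiplier
  }
  if (spec$opto_suppression < 1) {
    lt <- events[events$has_light, , drop = FALSE]
    if (nrow(lt)) {
      s_on <- lt$light_on_ms + spec$opto_latency
      s_off <- lt$light_off_ms
      idx <- findInterval(t, s_on)
      inwin <- idx >= 1L & idx <= length(s_on)
      inwin[inwin] <- t[inwin] <= s_off[idx[inwin]]
      r[inwin] <- r[inwin] * spec$opto_suppression
    }
  }
  if (spec$wer_amplitude > 0 || !is.null(spec$wer2)) {
    pf <- events[events$has_puff, , drop = FALSE]
    if (nrow(pf)) {
      defl <- pf$deflection_ms
      idx <- findInterval(t, defl)
      has <- idx >= 1L
      dt <- rep(NA_real_, length(t))
      dt[has] <- t[has] - defl[idx[has]]
      ok <- has & !is.na(dt)
      if (spec$wer_amplitude > 0) {
        r[ok] <- r[ok] + spec$wer_amplitude *
          wer_kernel(dt[ok], spec$wer_onset, spec$wer_peak, spec$wer_decay,
                     spec$wer_shape)
      }
      if (!is.null(spec$wer2)) {
        w2 <- spec$wer2
        r[ok] <- r[ok] + w2$amplitude *
          wer_kernel(dt[ok], w2$onset, w2$onset + .wer2_rise, w2$decay, "alpha")
      }
    }
  }
  r
}

#' Simulate one unit's spike train by Poisson thinning
#'
#' Draws an inhomogeneous Poisson realization of the [unit_rate()] model
#' over the session timeline, by thinning a homogeneous process at the
#' exact rate upper bound (baseline x whisking multiplier plus kernel
#' amplitudes), so the sampling is exact for any kernel shape.
#'
#' @param spec a [unit_spec()]
#' @param session session timeline (events, ground-truth states, duration)
#' @param seed integer seed for this unit's private stream
#' @return strictly increasing spike times, ms
#' @export
generate_unit_spiketrain <- function(spec, session, seed) {
  duration <- session$duration_ms
  rmax <- spec$base_rate * max(1, spec$whisking_multiplier) +
    spec$wer_amplitude + if (!is.null(spec$wer2)) spec$wer2$amplitude else 0
  if (rmax <= 0) return(numeric(0))
  withr::with_seed(as.integer(seed), {
    n <- rpois(1, rmax * duration / 1000)
    if (n == 0L) {
      numeric(0)
    } else {
      cand <- sort(runif(n, 0, duration))
      r <- unit_rate(cand, spec, session)
      if (any(r < 0)) stop("internal error: negative instantaneous rate")
      keep <- runif(n) < r / rmax
      unique(cand[keep])
    }
  })
}

#' Simulate the local field potential from ground-truth states
#'
#' During quiet intervals the LFP is a sinusoid at a frequency drawn from
#' the quiet band; during whisking, the sum of two sinusoids drawn from
#' the two active bands with matched total power. Broadband Gaussian
#' noise is added on top. Dominant spectral power therefore tracks the
#' behavioral state, which is what the state classifier consumes.
#'
#' @param state_truth a [state_intervals()] ground-truth segmentation
#' @param cfg a [state_config()]
#' @param seed integer seed
#' @return an `lfp_trace` object: `list(samples, fs)` with t0 = 0 ms
#' @export
generate_lfp <- function(state_truth, cfg, seed) {
  fs <- cfg$lfp_sample_rate
  duration_ms <- max(state_truth$end_ms)
  n <- ceiling(duration_ms / 1000 * fs)
  t_s <- (seq_len(n) - 1) / fs
  withr::with_seed(as.integer(seed), {
    x <- rnorm(n, 0, cfg$lfp_noise_sd)
    for (i in seq_len(nrow(state_truth))) {
      lo <- state_truth$start_ms[i] / 1000
      hi <- state_truth$end_ms[i] / 1000
      idx <- which(t_s >= lo & t_s < hi)
      if (!length(idx)) next
      if (state_truth$label[i] == "quiet") {
        f <- runif(1, cfg$quiet_band[1], cfg$quiet_band[2])
        ph <- runif(1, 0, 2 * pi)
        x[idx] <- x[idx] + cfg$osc_amplitude * sin(2 * pi * f * t_s[idx] + ph)
      } else if (state_truth$label[i] == "whisking") {
        amp <- cfg$osc_amplitude / sqrt(length(cfg$active_bands))
        for (band in cfg$active_bands) {
          f <- runif(1, band[1], band[2])
          ph <- runif(1, 0, 2 * pi)
          x[idx] <- x[idx] + amp * sin(2 * pi * f * t_s[idx] + ph)
        }
      }
    }
    structure(list(samples = x, fs = fs), class = "lfp_trace")
  })
}

#' Generate a complete synthetic recording session
#'
#' Builds the event log (condition blocks in seed-determined random
#' order per cycle), the ground-truth whisking/quiet episode structure,
#' the LFP, and one spike train per unit. Per-unit random streams are
#' derived deterministically from `(seed, unit_id)`, so adding a unit
#' never changes the others, and identical seeds give bit-identical
#' sessions.
#'
#' @param protocol a [protocol_config()]
#' @param units a list of [unit_spec()] objects (at least one)
#' @param states a [state_config()]
#' @return an object of class `whisk_session`: `events`, `units`
#'   (metadata data.frame), `unit_specs`, `spikes` (named list of spike
#'   time vectors, ms), `lfp`, `states_truth`, `duration_ms`, `protocol`,
#'   `state_cfg`, `seed`
#' @export
generate_session <- function(protocol, units, states = state_config()) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(states, "state_config"))
  if (!length(units)) stop("configuration error: empty unit list")
  if (!all(vapply(units, inherits, logical(1), "unit_spec")))
    stop("units must be a list of unit_spec objects")
  ids <- vapply(units, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop("configuration error: duplicate unit_id")
  if (abs(protocol$light_lead + protocol$puff_duration - protocol$light_duration) > 1e-9 &&
      protocol$light_duration == 70) {
    # default timing contract: the pulse ends together with the deflection
    warning("light_lead + puff_duration != light_duration; pulse does not end with the deflection")
  }

  interval_ms <- 1000 / protocol$puff_rate
  n_sweeps <- protocol$n_sweeps_per_condition *
    length(protocol$conditions) * protocol$n_cycles
  duration_ms <- n_sweeps * interval_ms + 1000

  sess <- withr::with_seed(protocol$seed, {
    events <- .build_event_log(protocol)
    truth <- .generate_state_truth(states, duration_ms)
    list(events = events, states_truth = truth)
  })
  sess$duration_ms <- duration_ms
  sess$lfp <- generate_lfp(sess$states_truth, states,
                           seed = seed_hash(protocol$seed, "lfp"))

  spikes <- lapply(units, function(u)
    generate_unit_spiketrain(u, sess, seed = seed_hash(protocol$seed, u$unit_id)))
  names(spikes) <- ids

  meta <- do.call(rbind, lapply(units, function(u) data.frame(
    unit_id = u$unit_id, structure = u$structure, depth_um = u$depth,
    base_rate = u$base_rate, whisking_multiplier = u$whisking_multiplier,
    opto_suppression = u$opto_suppression, opto_latency_ms = u$opto_latency,
    wer_amplitude = u$wer_amplitude, wer_onset_ms = u$wer_onset,
    wer_peak_ms = u$wer_peak, wer_decay_ms = u$wer_decay,
    wer_shape = u$wer_shape,
    wer2_onset_ms = if (is.null(u$wer2)) NA_real_ else u$wer2$onset,
    wer2_amplitude = if (is.null(u$wer2)) NA_real_ else u$wer2$amplitude,
    wer2_decay_ms = if (is.null(u$wer2)) NA_real_ else u$wer2$decay,
    is_tagged = u$is_tagged, is_interneuron = u$is_interneuron,
    peak_amplitude_asymmetry = u$waveform$peak_amplitude_asymmetry,
    trough_to_peak_ms = u$waveform$trough_to_peak,
    half_width_ms = u$waveform$half_width,
    stringsAsFactors = FALSE)))

  structure(list(
    events = sess$events,
    units = meta,
    unit_specs = stats::setNames(units, ids),
    spikes = spikes,
    lfp = sess$lfp,
    states_truth = sess$states_truth,
    duration_ms = duration_ms,
    protocol = protocol,
    state_cfg = states,
    seed = protocol$seed
  ), class = "whisk_session")
}

#' @export
print.whisk_session <- function(x, ...) {
  cat(sprintf("whisk_session: %d sweeps (%s), %d units, %.1f s, seed %d\n",
              nrow(x$events),
              paste(x$protocol$conditions, collapse = "/"),
              length(x$spikes), x$duration_ms / 1000, x$seed))
  invisible(x)
}
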