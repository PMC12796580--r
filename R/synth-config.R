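#' Stimulation protocol configuration
#'
#' Describes one recording session's sweep protocol: blocks of sweeps per
#' stimulation condition (light only, air puff only, or both), repeated
#' over cycles with the block order randomized within each cycle. The
#' defaults reproduce the standard awake-mouse protocol: thirty sweeps
#' per condition, 25 puff trials of 20 ms at 0.5 Hz, air travel delay of
#' about 10 ms from trigger to whisker, and a 70 ms light pulse that
#' starts 50 ms before the deflection reaches the whiskers (so the pulse
#' ends together with the deflection).
#'
#' @param n_sweeps_per_condition sweeps per condition block (default 30)
#' @param conditions character vector drawn from
#'   `c("opto_only", "puff_only", "combined")`
#' @param n_cycles number of repetitions of the full condition cycle
#' @param puff_count nominal deflections per block (protocol metadata;
#'   the realized per-state sweep counts emerge from state filtering)
#' @param puff_duration air-puff duration, ms
#' @param puff_rate sweep repetition rate, Hz (0.5 Hz = one sweep per 2 s)
#' @param air_delay trigger-to-whisker air travel time, ms
#' @param light_duration light-pulse duration, ms (70, alternatively 120)
#' @param light_lead light onset lead before deflection onset, ms
#' @param seed integer seed; the whole session derives from it
#' @return an object of class `protocol_config`
#' @export
protocol_config <- function(n_sweeps_per_condition = 30L,
                            conditions = c("opto_only", "puff_only", "combined"),
                            n_cycles = 2L,
                            puff_count = 25L,
                            puff_duration = 20,
                            puff_rate = 0.5,
                            air_delay = 10,
                            light_duration = 70,
                            light_lead = 50,
                            seed = 1L) {
  conditions <- match.arg(conditions,
                          c("opto_only", "puff_only", "combined"),
                          several.ok = TRUE)
  if (n_sweeps_per_condition < 1L)
    stop("configuration error: n_sweeps_per_condition must be >= 1")
  if (light_lead < 0)
    stop("configuration error: light_lead must be >= 0")
  if (any(c(puff_duration, puff_rate, air_delay, light_duration) <= 0))
    stop("configuration error: all durations and rates must be > 0")
  if (n_cycles < 1L) stop("configuration error: n_cycles must be >= 1")
  structure(list(
    n_sweeps_per_condition = as.integer(n_sweeps_per_condition),
    conditions = conditions,
    n_cycles = as.integer(n_cycles),
    puff_count = as.integer(puff_count),
    puff_duration = puff_duration,
    puff_rate = puff_rate,
    air_delay = air_delay,
    light_duration = light_duration,
    light_lead = light_lead,
    seed = as.integer(seed)
  ), class = "protocol_config")
}

#' Extracellular waveform features of a unit
#'
#' The three scalar features used to separate fast-spiking putative
#' interneurons from excitatory cells.
#'
#' @param peak_amplitude_asymmetry dimensionless asymmetry of the two
#'   positive peaks around the trough
#' @param trough_to_peak trough-to-peak latency, ms
#' @param half_width spike half-width, ms
#' @return an object of class `waveform_features`
#' @export
waveform_features <- function(peak_amplitude_asymmetry,
                              trough_to_peak,
                              half_width) {
  if (trough_to_peak <= 0 || half_width <= 0)
    stop("configuration error: trough_to_peak and half_width must be > 0")
  structure(list(
    peak_amplitude_asymmetry = peak_amplitude_asymmetry,
    trough_to_peak = trough_to_peak,
    half_width = half_width
  ), class = "waveform_features")
}

#' Specification of one simulated unit
#'
#' Rate model: an inhomogeneous Poisson process with
#' `r(t) = base_rate * whisking_multiplier^[t in whisking] *
#' opto_suppression^[t in suppression window] + WER kernels`, where the
#' suppression window of each light sweep is
#' `[light_on + opto_latency, light_off]` and the whisker-evoked response
#' (WER) kernel is added at each deflection. The default kernel
#' (`wer_shape = "alpha"`) rises linearly from `wer_onset` to `wer_peak`
#' and decays exponentially with time constant `wer_decay`; a `"boxcar"`
#' kernel holds constant amplitude on `[wer_onset, wer_peak]`. An optional
#' second component (`wer2`) models the late response of first-order
#' thalamic (VPM-like) units.
#'
#' @param unit_id unique identifier string
#' @param structure one of `"S1"`, `"POm"`, `"VPM"`
#' @param depth recording depth in micrometers (used for cortical layer
#'   assignment of S1 units)
#' @param base_rate spontaneous rate during quiet non-whisking, spikes/s
#' @param whisking_multiplier rate multiplier during whisking (>= 1)
#' @param opto_suppression multiplicative rate factor in `[0, 1]` during
#'   effective photoinactivation (1 = unaffected)
#' @param opto_latency latency from light onset to suppression, ms
#' @param wer_amplitude peak amplitude of the evoked-rate kernel, spikes/s
#' @param wer_onset,wer_peak,wer_decay kernel shape parameters, ms
#' @param wer_shape `"alpha"` (linear rise, exponential decay) or
#'   `"boxcar"` (constant on `[onset, peak]`)
#' @param wer2 optional late component: `list(onset, amplitude, decay)`
#' @param is_tagged ground-truth membership of the photoinactivated
#'   (transfected) population
#' @param is_interneuron ground-truth fast-spiking interneuron flag
#' @param waveform a [waveform_features()] object
#' @return an object of class `unit_spec`
#' @export
unit_spec <- function(unit_id,
                      structure = c("S1", "POm", "VPM"),
                      depth = NA_real_,
                      base_rate = 5,
                      whisking_multiplier = 1,
                      opto_suppression = 1,
                      opto_latency = 0,
                      wer_amplitude = 0,
                      wer_onset = 6,
                      wer_peak = 12,
                      wer_decay = 10,
                      wer_shape = c("alpha", "boxcar"),
                      wer2 = NULL,
                      is_tagged = FALSE,
                      is_interneuron = FALSE,
                      waveform = waveform_features(0.10, 0.50, 0.30)) {
  structure <- match.arg(structure)
  wer_shape <- match.arg(wer_shape)
  if (base_rate < 0) stop("configuration error: base_rate must be >= 0")
  if (opto_latency < 0) stop("configuration error: opto_latency must be >= 0")
  if (opto_suppression < 0 || opto_suppression > 1)
    stop("configuration error: opto_suppression must be in [0, 1]")
  if (whisking_multiplier < 1)
    stop("configuration error: whisking_multiplier must be >= 1")
  if (wer_amplitude > 0 && wer_onset >= wer_peak)
    stop("configuration error: wer_onset must precede wer_peak")
  if (!is.null(wer2)) {
    stopifnot(all(c("onset", "amplitude", "decay") %in% names(wer2)))
    if (wer2$onset <= wer_peak)
      stop("configuration error: second WER component must start after the first component's peak")
  }
  base::structure(list(
    unit_id = as.character(unit_id),
    structure = structure,
    depth = depth,
    base_rate = base_rate,
    whisking_multiplier = whisking_multiplier,
    opto_suppression = opto_suppression,
    opto_latency = opto_latency,
    wer_amplitude = wer_amplitude,
    wer_onset = wer_onset,
    wer_peak = wer_peak,
    wer_decay = wer_decay,
    wer_shape = wer_shape,
    wer2 = wer2,
    is_tagged = isTRUE(is_tagged),
    is_interneuron = isTRUE(is_interneuron),
    waveform = waveform
  ), class = "unit_spec")
}

#' Brain-state and LFP configuration
#'
#' Controls the alternating whisking/quiet episode structure and the
#' band-limited LFP that tracks it. Episode durations are exponential
#' with the given means, truncated below at `min_bout`. During quiet
#' episodes the LFP oscillates at a frequency drawn from `quiet_band`
#' (4-12 Hz); during whisking at frequencies drawn from the two
#' `active_bands` (13-30 and 25-60 Hz), with matched total oscillatory
#' power, plus broadband Gaussian noise.
#'
#' @param quiet_mean_ms mean quiet-episode duration, ms
#' @param whisk_mean_ms mean whisking-episode duration, ms; 0 produces an
#'   all-quiet session
#' @param min_bout minimum episode duration, ms
#' @param quiet_band quiet-state LFP band, Hz
#' @param active_bands list of active-state LFP bands, Hz
#' @param lfp_sample_rate LFP sampling rate, Hz
#' @param lfp_noise_sd broadband noise standard deviation (signal units)
#' @param osc_amplitude oscillation amplitude (signal units)
#' @return an object of class `state_config`
#' @export
state_config <- function(quiet_mean_ms = 3000,
                         whisk_mean_ms = 2000,
                         min_bout = 500,
                         quiet_band = c(4, 12),
                         active_bands = list(c(13, 30), c(25, 60)),
                         lfp_sample_rate = 1000,
                         lfp_noise_sd = 0.5,
                         osc_amplitude = 1) {
  if (length(quiet_band) != 2L || diff(quiet_band) < 0)
    stop("configuration error: quiet_band must be an increasing Hz interval")
  if (!length(active_bands))
    stop("configuration error: active_bands must be non-empty")
  hi <- max(quiet_band[2], vapply(active_bands, max, numeric(1)))
  if (lfp_sample_rate <= 2 * hi)
    stop("configuration error: lfp_sample_rate must exceed twice the highest band edge")
  structure(list(
    quiet_mean_ms = quiet_mean_ms,
    whisk_mean_ms = whisk_mean_ms,
    min_bout = min_bout,
    quiet_band = quiet_band,
    active_bands = active_bands,
    lfp_sample_rate = lfp_sample_rate,
    lfp_noise_sd = lfp_noise_sd,
    osc_amplitude = osc_amplitude
  ), class = "state_config")
}

#' Labeled brain-state intervals
#'
#' @param start_ms,end_ms interval bounds, ms
#' @param label one of `"quiet"`, `"whisking"`, `"excluded"` per interval
#' @param provenance `"truth"` (simulated ground truth) or `"classified"`
#'   (LFP-derived)
#' @return a `data.frame` of class `state_intervals` with attributes
#' @export
state_intervals <- function(start_ms, end_ms,
                            label,
                            provenance = c("truth", "classified")) {
  provenance <- match.arg(provenance)
  stopifnot(length(start_ms) == length(end_ms),
            length(label) == length(start_ms))
  if (any(!label %in% c("quiet", "whisking", "excluded")))
    stop("state labels must be quiet/whisking/excluded")
  if (length(start_ms)) {
    o <- order(start_ms)
    start_ms <- start_ms[o]; end_ms <- end_ms[o]; label <- label[o]
    if (any(end_ms <= start_ms)) stop("empty or inverted state interval")
    if (length(start_ms) > 1L && any(start_ms[-1] < end_ms[-length(end_ms)] - 1e-9))
      stop("state intervals must not overlap")
  }
  out <- data.frame(start_ms = start_ms, end_ms = end_ms,
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("state_intervals", "data.frame")
  out
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("protocol: %d sweeps x %s x %d cycle(s), puff %g ms @ %g Hz, light %g ms (lead %g ms), air delay %g ms, seed %d\n",
              x$n_sweeps_per_condition, paste(x$conditions, collapse = "/"),
              x$n_cycles, x$puff_duration, x$puff_rate, x$light_duration,
              x$light_lead, x$air_delay, x$seed))
  invisible(x)
}
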