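#' Write a session to the documented CSV directory layout
#'
#' Creates `events.csv`, `units.csv`, `spikes.csv`, `lfp.csv` and
#' `states_truth.csv` under `dir`, plus `session.json` with protocol and
#' state-model metadata. The layout is plain text so sessions can be
#' inspected, versioned, or consumed by other tools.
#'
#' @param session a `whisk_session`
#' @param dir output directory (created if needed)
#' @param lfp include the (large) LFP samples file (default TRUE)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir, lfp = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(session$units, file.path(dir, "units.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(names(session$spikes), function(id) {
    if (!length(session$spikes[[id]])) return(NULL)
    data.frame(unit_id = id, time_ms = session$spikes[[id]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0), time_ms = numeric(0))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  st <- as.data.frame(session$states_truth)
  write.csv(st, file.path(dir, "states_truth.csv"), row.names = FALSE)
  if (lfp) {
    write.csv(data.frame(sample = session$lfp$samples),
              file.path(dir, "lfp.csv"), row.names = FALSE)
  }
  meta <- list(
    duration_ms = session$duration_ms,
    seed = session$seed,
    lfp_fs = session$lfp$fs,
    protocol = unclass(session$protocol),
    state_cfg = lapply(unclass(session$state_cfg), function(v) v)
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from the CSV directory layout
#'
#' Inverse of [write_session()]. Unit specifications are reconstructed
#' from the scalar columns of `units.csv`, so a round-tripped session
#' supports the full analysis pipeline.
#'
#' @param dir directory produced by [write_session()]
#' @return a `whisk_session`
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  events <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  units <- read.csv(file.path(dir, "units.csv"), stringsAsFactors = FALSE)
  spikes_df <- read.csv(file.path(dir, "spikes.csv"), stringsAsFactors = FALSE)
  st <- read.csv(file.path(dir, "states_truth.csv"), stringsAsFactors = FALSE)
  lfp_path <- file.path(dir, "lfp.csv")
  lfp <- if (file.exists(lfp_path)) {
    structure(list(samples = read.csv(lfp_path)$sample, fs = meta$lfp_fs),
              class = "lfp_trace")
  } else NULL
  spikes <- lapply(units$unit_id, function(id)
    sort(spikes_df$time_ms[spikes_df$unit_id == id]))
  names(spikes) <- units$unit_id
  specs <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    unit_spec(
      unit_id = u$unit_id, structure = u$structure, depth = u$depth_um,
      base_rate = u$base_rate, whisking_multiplier = u$whisking_multiplier,
      opto_suppression = u$opto_suppression, opto_latency = u$opto_latency_ms,
      wer_amplitude = u$wer_amplitude, wer_onset = u$wer_onset_ms,
      wer_peak = u$wer_peak_ms, wer_decay = u$wer_decay_ms,
      wer_shape = u$wer_shape,
      wer2 = if (is.na(u$wer2_onset_ms)) NULL else
        list(onset = u$wer2_onset_ms, amplitude = u$wer2_amplitude,
             decay = u$wer2_decay_ms),
      is_tagged = u$is_tagged, is_interneuron = u$is_interneuron,
      waveform = waveform_features(u$peak_amplitude_asymmetry,
                                   u$trough_to_peak_ms, u$half_width_ms))
  })
  names(specs) <- units$unit_id
  proto <- do.call(protocol_config, meta$protocol[names(meta$protocol) != "conditions"])
  proto$conditions <- unlist(meta$protocol$conditions)
  scfg <- meta$state_cfg
  if (is.matrix(scfg$active_bands)) {
    scfg$active_bands <- lapply(seq_len(nrow(scfg$active_bands)),
                                function(i) scfg$active_bands[i, ])
  }
  structure(list(
    events = events, units = units, unit_specs = specs, spikes = spikes,
    lfp = lfp,
    states_truth = state_intervals(st$start_ms, st$end_ms, st$label,
                                   provenance = "truth"),
    duration_ms = meta$duration_ms,
    protocol = proto,
    state_cfg = do.call(state_config, scfg),
    seed = meta$seed
  ), class = "whisk_session")
}
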