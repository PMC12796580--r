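#' Default synthetic unit population
#'
#' A fixed population emulating simultaneous S1 + thalamus laminar-probe
#' recordings during photoinactivation of layer-6 corticothalamic cells:
#' opto-tagged L6 units (short-latency suppression), non-tagged cells in
#' L2/3-L6, two fast-spiking interneurons, higher-order thalamic (POm)
#' units suppressed through the corticothalamic loop at ~10 ms latency,
#' and first-order thalamic (VPM) units with a biphasic whisker-evoked
#' response (early component from ~5 ms, late component from ~41 ms).
#' Baseline rates, whisking multipliers (roughly 2-3x) and suppression
#' factors follow the magnitudes typical of awake-mouse recordings in
#' these structures.
#'
#' @param n_tagged,n_l6_other,n_other_layers,n_interneurons,n_pom,n_vpm
#'   group sizes
#' @param suppression_tagged,suppression_pom,suppression_vpm
#'   photoinactivation rate multipliers per group (1 = unaffected)
#' @param latency_tagged,latency_thalamus suppression latencies, ms
#' @return list of [unit_spec()] objects
#' @export
default_unit_population <- function(n_tagged = 8L,
                                    n_l6_other = 6L,
                                    n_other_layers = 6L,
                                    n_interneurons = 2L,
                                    n_pom = 10L,
                                    n_vpm = 6L,
                                    suppression_tagged = 0.35,
                                    suppression_pom = 0.55,
                                    suppression_vpm = 0.40,
                                    latency_tagged = 2,
                                    latency_thalamus = 10) {
  units <- list()
  add <- function(u) units[[length(units) + 1L]] <<- u
  if (n_tagged > 0) for (i in seq_len(n_tagged)) {
    add(unit_spec(sprintf("s1l6_tag%02d", i), "S1",
                  depth = 800 + 20 * (i - 1),
                  base_rate = seq(3, 8, length.out = max(2, n_tagged))[min(i, max(2, n_tagged))],
                  whisking_multiplier = 3,
                  opto_suppression = suppression_tagged,
                  opto_latency = latency_tagged,
                  wer_amplitude = 60, wer_onset = 8, wer_peak = 14,
                  wer_decay = 10, is_tagged = TRUE))
  }
  if (n_l6_other > 0) for (i in seq_len(n_l6_other)) {
    add(unit_spec(sprintf("s1l6_oth%02d", i), "S1",
                  depth = 780 + 30 * (i - 1),
                  base_rate = 1.5 + 0.4 * (i - 1),
                  whisking_multiplier = 3,
                  wer_amplitude = 50, wer_onset = 8, wer_peak = 14,
                  wer_decay = 10))
  }
  if (n_other_layers > 0) {
    depths <- rep(c(150, 250, 350, 450, 600, 700),
                  length.out = n_other_layers)
    for (i in seq_len(n_other_layers)) {
      add(unit_spec(sprintf("s1up_%02d", i), "S1", depth = depths[i],
                    base_rate = 2.5 + 0.5 * (i %% 4),
                    whisking_multiplier = 2,
                    wer_amplitude = 60, wer_onset = 7, wer_peak = 13,
                    wer_decay = 10))
    }
  }
  if (n_interneurons > 0) for (i in seq_len(n_interneurons)) {
    add(unit_spec(sprintf("s1_int%02d", i), "S1", depth = 400 + 200 * (i - 1),
                  base_rate = 10, whisking_multiplier = 2,
                  wer_amplitude = 40, wer_onset = 7, wer_peak = 12,
                  wer_decay = 8, is_interneuron = TRUE,
                  waveform = waveform_features(0.20, 0.25, 0.15)))
  }
  if (n_pom > 0) for (i in seq_len(n_pom)) {
    add(unit_spec(sprintf("pom_%02d", i), "POm", depth = 4000,
                  base_rate = seq(5, 9, length.out = max(2, n_pom))[min(i, max(2, n_pom))],
                  whisking_multiplier = 1.9,
                  opto_suppression = suppression_pom,
                  opto_latency = latency_thalamus,
                  wer_amplitude = 80, wer_onset = 6, wer_peak = 12,
                  wer_decay = 12))
  }
  if (n_vpm > 0) for (i in seq_len(n_vpm)) {
    add(unit_spec(sprintf("vpm_%02d", i), "VPM", depth = 3800,
                  base_rate = 4 + 0.5 * (i - 1),
                  whisking_multiplier = 2.2,
                  opto_suppression = suppression_vpm,
                  opto_latency = latency_thalamus,
                  wer_amplitude = 100, wer_onset = 5, wer_peak = 10,
                  wer_decay = 8,
                  wer2 = list(onset = 41, amplitude = 30, decay = 20)))
  }
  units
}

#' Pipeline run configuration
#'
#' Bundles everything a run needs; a run is reproducible from this
#' object alone.
#'
#' @param seed integer master seed (overrides the protocol seed)
#' @param protocol a [protocol_config()]
#' @param states a [state_config()]
#' @param units list of [unit_spec()] objects
#' @param psth_window PSTH window around the deflection, ms
#' @param bin_width PSTH bin width, ms
#' @param spont_window spontaneous-rate window (light onset to
#'   deflection), ms relative to the deflection
#' @param evoked_window whisker-evoked response window, ms
#' @param early,late biphasic split windows, ms
#' @param sweep_state_window window that must be state-pure for a sweep
#'   to keep its label, ms
#' @param ratio_threshold,min_episode state-classifier parameters
#' @param design ANOVA design flag (`"both_within"` or `"mixed"`)
#' @param group_by `"classified"` groups units by the opto-tag
#'   classifier's output; `"truth"` groups by simulated ground truth
#'   (used for parameter-recovery evaluation, where classifier error
#'   should not contaminate rate estimates)
#' @param rout_q ROUT false-discovery rate, percent
#' @param min_sweeps minimum sweeps per condition and state for a unit
#'   to contribute that state's metrics
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @return an object of class `run_config`
#' @export
run_config <- function(seed = 1L,
                       protocol = protocol_config(),
                       states = state_config(),
                       units = default_unit_population(),
                       psth_window = c(-200, 100),
                       bin_width = 2,
                       spont_window = c(-50, 0),
                       evoked_window = c(0, 100),
                       early = c(5, 40),
                       late = c(41, 100),
                       sweep_state_window = c(-200, 100),
                       ratio_threshold = 1.5,
                       min_episode = 500,
                       design = c("both_within", "mixed"),
                       group_by = c("classified", "truth"),
                       rout_q = 1,
                       min_sweeps = 3L,
                       out_dir = NULL) {
  design <- match.arg(design)
  group_by <- match.arg(group_by)
  protocol$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), protocol = protocol,
                 states = states, units = units,
                 psth_window = psth_window, bin_width = bin_width,
                 spont_window = spont_window, evoked_window = evoked_window,
                 early = early, late = late,
                 sweep_state_window = sweep_state_window,
                 ratio_threshold = ratio_threshold,
                 min_episode = min_episode,
                 design = design, group_by = group_by,
                 rout_q = rout_q, min_sweeps = as.integer(min_sweeps),
                 out_dir = out_dir), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.unit_group <- function(structure_, tagged, layer) {
  if (structure_ != "S1") return(structure_)
  if (isTRUE(tagged)) return("S1L6-tagged")
  paste0("S1-", layer)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Simulate -> segment states -> label sweeps -> classify units ->
#' quantify responses -> apply exclusions (interneurons, unclassifiable
#' units, robust outliers) -> run the statistical battery, and write
#' summary/metrics/statistics CSVs plus a JSON run log when `out_dir`
#' is set.
#'
#' @param cfg a [run_config()]
#' @return list with `summary`, `metrics`, `classification`, `stats`
#'   (per group and state), `exclusions`, `sweep_census`, `session`,
#'   `sweep_labels`, `psths`, `log`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!length(cfg$units))
    stop("pipeline stage 'synth' failed: empty unit population")

  session <- .stage("synth",
                    generate_session(cfg$protocol, cfg$units, cfg$states))
  spg <- .stage("states", compute_spectrogram(session$lfp))
  cls <- .stage("states", classify_states(
    spg, quiet_band = cfg$states$quiet_band,
    active_bands = cfg$states$active_bands,
    ratio_threshold = cfg$ratio_threshold,
    min_episode = cfg$min_episode))
  sweep_labels <- .stage("states", assign_sweep_states(
    cls, session, cfg$sweep_state_window))

  ev <- session$events
  census <- as.data.frame(table(condition = ev$condition,
                                state = sweep_labels))

  # --- unit classification -------------------------------------------------
  light_events <- ev$light_on_ms[ev$condition == "opto_only"]
  classification <- .stage("classify", {
    rows <- lapply(session$unit_specs, function(u) {
      spk <- session$spikes[[u$unit_id]]
      tag <- "unclassifiable"
      baseline <- NA_real_
      if (length(light_events)) {
        pl <- build_psth(spk, light_events,
                         window = c(-200, 120), bin_width = cfg$bin_width,
                         alignment = "light_on")
        tag <- classify_optotag(pl, pulse_window = c(0, cfg$protocol$light_duration))
        starts <- head(pl$bin_edges, -1); ends <- tail(pl$bin_edges, -1)
        baseline <- mean(pl$rate[starts >= -200 & ends <= 0])
      }
      layer <- if (u$structure == "S1") assign_layer(u$depth) else u$structure
      inter <- classify_interneuron(u$waveform)
      tagged <- if (cfg$group_by == "truth") u$is_tagged else tag == "tagged"
      data.frame(unit_id = u$unit_id, structure = u$structure,
                 layer = layer, optotag = tag, tagged = tagged,
                 interneuron = inter, baseline_rate = baseline,
                 group = .unit_group(u$structure, tagged, layer),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(classification) <- NULL

  excl <- stats::setNames(rep("analyzed", nrow(classification)),
                          classification$unit_id)
  excl[classification$interneuron] <- "interneuron"
  drop_unclass <- classification$optotag == "unclassifiable" &
    cfg$group_by == "classified" & classification$structure == "S1"
  excl[drop_unclass & excl == "analyzed"] <- "unclassifiable"

  keep_ids <- names(excl)[excl == "analyzed"]
  if (!length(keep_ids))
    stop("pipeline stage 'classify' failed: zero units surviving exclusion")

  # --- response metrics ----------------------------------------------------
  psths <- list()
  metrics <- .stage("metrics", {
    rows <- list()
    for (id in keep_ids) {
      spk <- session$spikes[[id]]
      grp <- classification$group[classification$unit_id == id]
      for (st in c("quiet", "whisking")) {
        ctrl_ev <- ev$deflection_ms[ev$condition == "puff_only" &
                                      sweep_labels == st]
        opto_ev <- ev$deflection_ms[ev$condition == "combined" &
                                      sweep_labels == st]
        if (length(ctrl_ev) < cfg$min_sweeps ||
            length(opto_ev) < cfg$min_sweeps) next
        p_ctrl <- build_psth(spk, ctrl_ev, cfg$psth_window, cfg$bin_width,
                             state_label = st)
        p_opto <- build_psth(spk, opto_ev, cfg$psth_window, cfg$bin_width,
                             state_label = st)
        psths[[id]][[st]] <- list(ctrl = p_ctrl, opto = p_opto)
        rm_ <- response_metrics(p_ctrl, evoked_window = cfg$evoked_window,
                                early = cfg$early, late = cfg$late)
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = id, group = grp, state = st,
          n_ctrl = length(ctrl_ev), n_opto = length(opto_ev),
          spont_ctrl = window_rate(spk, ctrl_ev, cfg$spont_window),
          spont_opto = window_rate(spk, opto_ev, cfg$spont_window),
          wer_ctrl = window_rate(spk, ctrl_ev, cfg$evoked_window),
          wer_opto = window_rate(spk, opto_ev, cfg$evoked_window),
          onset_latency = rm_$onset_latency, peak_rate = rm_$peak_rate,
          peak_time = rm_$peak_time, slope = rm_$slope,
          wer1_rate = rm_$wer1_rate, wer2_rate = rm_$wer2_rate,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) stop("no unit has enough sweeps in any state")
    df$spont_delta <- df$spont_ctrl - df$spont_opto
    df$wer_delta <- df$wer_ctrl - df$wer_opto
    df
  })

  # --- robust outlier removal on quiet-state suppression deltas ------------
  outlier_ids <- .stage("stats", {
    flagged <- character(0)
    q <- metrics[metrics$state == "quiet", , drop = FALSE]
    for (grp in unique(q$group)) {
      gi <- q[q$group == grp, , drop = FALSE]
      if (nrow(gi) >= 3L) {
        mask <- rout_outliers(gi$spont_delta, Q = cfg$rout_q)
        flagged <- c(flagged, gi$unit_id[mask])
      }
    }
    unique(flagged)
  })
  excl[outlier_ids] <- "outlier"
  metrics <- metrics[!metrics$unit_id %in% outlier_ids, , drop = FALSE]
  keep_ids <- setdiff(keep_ids, outlier_ids)
  if (!length(keep_ids))
    stop("pipeline stage 'stats' failed: zero units surviving exclusion")

  # --- statistical battery -------------------------------------------------
  stats_out <- .stage("stats", {
    out <- list()
    for (grp in unique(metrics$group)) {
      for (st in unique(metrics$state[metrics$group == grp])) {
        gi <- metrics[metrics$group == grp & metrics$state == st, ,
                      drop = FALSE]
        if (nrow(gi) < 2L) next
        tab <- rbind(
          data.frame(subject = gi$unit_id, row = "spont", col = "ctrl",
                     value = gi$spont_ctrl),
          data.frame(subject = gi$unit_id, row = "spont", col = "opto",
                     value = gi$spont_opto),
          data.frame(subject = gi$unit_id, row = "wer", col = "ctrl",
                     value = gi$wer_ctrl),
          data.frame(subject = gi$unit_id, row = "wer", col = "opto",
                     value = gi$wer_opto))
        an <- two_way_rm_anova(tab, design = cfg$design)
        paired <- t_tests(gi$spont_ctrl, gi$spont_opto, "paired")
        out[[paste(grp, st, sep = "|")]] <- list(
          group = grp, state = st, n = nrow(gi), anova = an,
          paired_spont = paired)
      }
    }
    out
  })

  # --- summary table -------------------------------------------------------
  sem <- function(x) sd(x) / sqrt(length(x))
  summary_rows <- list()
  for (grp in unique(metrics$group)) {
    for (st in unique(metrics$state[metrics$group == grp])) {
      gi <- metrics[metrics$group == grp & metrics$state == st, ,
                    drop = FALSE]
      for (measure in c("spont", "wer")) {
        for (cond in c("ctrl", "opto")) {
          v <- gi[[paste(measure, cond, sep = "_")]]
          summary_rows[[length(summary_rows) + 1L]] <- data.frame(
            group = grp, state = st, measure = measure, condition = cond,
            mean_rate = mean(v), sem_rate = sem(v), n_units = nrow(gi),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  summary_df <- do.call(rbind, summary_rows)

  exclusions <- data.frame(unit_id = names(excl), reason = unname(excl),
                           stringsAsFactors = FALSE)
  log <- list(seed = cfg$seed,
              n_units_in = nrow(classification),
              n_analyzed = sum(excl == "analyzed"),
              n_interneurons = sum(excl == "interneuron"),
              n_unclassifiable = sum(excl == "unclassifiable"),
              n_outliers = sum(excl == "outlier"),
              sweep_census = census)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary_df, file.path(cfg$out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(classification, file.path(cfg$out_dir, "units_classified.csv"),
              row.names = FALSE)
    write.csv(exclusions, file.path(cfg$out_dir, "exclusions.csv"),
              row.names = FALSE)
    eff <- do.call(rbind, lapply(stats_out, function(s) {
      cbind(group = s$group, state = s$state, n = s$n, s$anova$effects)
    }))
    if (!is.null(eff))
      write.csv(eff, file.path(cfg$out_dir, "anova_effects.csv"),
                row.names = FALSE)
    ph <- do.call(rbind, lapply(stats_out, function(s) {
      cbind(group = s$group, state = s$state, s$anova$posthoc)
    }))
    if (!is.null(ph))
      write.csv(ph, file.path(cfg$out_dir, "anova_posthoc.csv"),
                row.names = FALSE)
    jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(summary = summary_df, metrics = metrics,
       classification = classification, stats = stats_out,
       exclusions = exclusions, sweep_census = census,
       session = session, sweep_labels = sweep_labels,
       states_classified = cls, psths = psths, log = log)
}

#' Render averaged-PSTH report figures
#'
#' One figure per (group, state): the across-unit mean control and
#' photoinactivation PSTHs with SEM confidence bands, written as PNG
#' files with deterministic names.
#'
#' @param result output of [run_pipeline()]
#' @param fig_dir output directory
#' @return data.frame of written figure files and their underlying
#'   averaged curves (invisible access for testing)
#' @export
make_report <- function(result, fig_dir) {
  if (is.null(result$psths) || !length(result$psths))
    stop("input error: pipeline result contains no PSTHs")
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- result$classification
  files <- list()
  curves <- list()
  combos <- unique(result$metrics[, c("group", "state")])
  for (i in seq_len(nrow(combos))) {
    grp <- combos$group[i]; st <- combos$state[i]
    ids <- result$metrics$unit_id[result$metrics$group == grp &
                                    result$metrics$state == st]
    ids <- ids[vapply(ids, function(id) !is.null(result$psths[[id]][[st]]),
                      logical(1))]
    if (!length(ids)) next
    get_mat <- function(cond) do.call(rbind, lapply(ids, function(id)
      result$psths[[id]][[st]][[cond]]$rate))
    ctr <- psth_centers(result$psths[[ids[1]]][[st]]$ctrl)
    mc <- get_mat("ctrl"); mo <- get_mat("opto")
    sem <- function(m) {
      if (nrow(m) < 2L) return(numeric(ncol(m)))
      apply(m, 2, sd) / sqrt(nrow(m))
    }
    df <- rbind(
      data.frame(time_ms = ctr, rate = colMeans(mc), sem = sem(mc),
                 condition = "control"),
      data.frame(time_ms = ctr, rate = colMeans(mo), sem = sem(mo),
                 condition = "photoinactivation"))
    slug <- gsub("[^A-Za-z0-9]+", "-", paste(grp, st))
    path <- file.path(fig_dir, sprintf("psth_%s.png", slug))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = time_ms, y = rate,
                                           color = condition,
                                           fill = condition)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = rate - sem,
                                        ymax = rate + sem),
                           alpha = 0.25, color = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time from deflection (ms)", y = "rate (spikes/s)",
                    title = sprintf("%s, %s state (n = %d units)",
                                    grp, st, length(ids))) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(path, gg, width = 6, height = 4, dpi = 120)
    files[[length(files) + 1L]] <- data.frame(group = grp, state = st,
                                              file = path,
                                              stringsAsFactors = FALSE)
    curves[[paste(grp, st, sep = "|")]] <- df
  }
  out <- do.call(rbind, files)
  attr(out, "curves") <- curves
  out
}
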