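#!/usr/bin/env Rscript

# Step 4 - quantify whisker-evoked responses.
#
# Per unit, state and condition: spontaneous rate in the light lead-in
# window (light onset to deflection), evoked rate over 0-100 ms, onset
# latency (baseline + 2 SD for >= 5 consecutive 2-ms bins), slope from
# onset to the maximum peak, and the early/late biphasic split (5-40 /
# 41-100 ms) that characterizes first-order (VPM-like) responses.

library(whiskloop)

session <- read_session("results/session")
sweeps <- read.csv("results/sweep_states.csv")
ev <- session$events
labels <- sweeps$state

rows <- list()
for (id in names(session$spikes)) {
  spk <- session$spikes[[id]]
  for (st in c("quiet", "whisking")) {
    ctrl_ev <- ev$deflection_ms[ev$condition == "puff_only" & labels == st]
    opto_ev <- ev$deflection_ms[ev$condition == "combined" & labels == st]
    if (length(ctrl_ev) < 3 || length(opto_ev) < 3) next
    p_ctrl <- build_psth(spk, ctrl_ev, c(-200, 100), 2, state_label = st)
    m <- response_metrics(p_ctrl)
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = id, structure = session$units$structure[
        session$units$unit_id == id],
      state = st, n_ctrl = length(ctrl_ev), n_opto = length(opto_ev),
      spont_ctrl = window_rate(spk, ctrl_ev, c(-50, 0)),
      spont_opto = window_rate(spk, opto_ev, c(-50, 0)),
      wer_ctrl = window_rate(spk, ctrl_ev, c(0, 100)),
      wer_opto = window_rate(spk, opto_ev, c(0, 100)),
      onset_ms = m$onset_latency, peak_rate = m$peak_rate,
      peak_time_ms = m$peak_time, slope = m$slope,
      wer1_rate = m$wer1_rate, wer2_rate = m$wer2_rate,
      stringsAsFactors = FALSE)
  }
}
metrics <- do.call(rbind, rows)
metrics$spont_delta <- metrics$spont_ctrl - metrics$spont_opto
write.csv(metrics, "results/metrics.csv", row.names = FALSE)

cat(sprintf("metrics for %d (unit, state) combinations\n", nrow(metrics)))
for (strc in c("S1", "POm", "VPM")) {
  mi <- metrics[metrics$structure == strc & metrics$state == "quiet", ]
  if (!nrow(mi)) next
  cat(sprintf("  %-4s quiet: onset %4.1f ms (median), WER %5.1f spikes/s, spont delta %4.2f spikes/s\n",
              strc, median(mi$onset_ms, na.rm = TRUE),
              mean(mi$wer_ctrl), mean(mi$spont_delta)))
}
vpm <- metrics[metrics$structure == "VPM", ]
cat(sprintf("  VPM biphasic split: early %5.1f, late %5.1f spikes/s\n",
            mean(vpm$wer1_rate), mean(vpm$wer2_rate)))
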