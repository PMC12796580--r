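#!/usr/bin/env Rscript

# Step 2 - segment brain state from the LFP spectrogram.
#
# Reads the session written by 01_simulate.R, computes the sliding
# Welch spectrogram, classifies each window from the active/quiet
# band-power ratio (4-12 Hz quiet band vs. the 13-30 / 25-60 Hz active
# bands), labels sweeps whose analysis window is state-pure, and writes
# the classified intervals plus per-sweep labels. Since the session is
# synthetic, the script also reports agreement with ground truth.

library(whiskloop)

session <- read_session("results/session")
spg <- compute_spectrogram(session$lfp)
cls <- classify_states(spg)
write.csv(as.data.frame(cls), "results/states_classified.csv",
          row.names = FALSE)

labels <- assign_sweep_states(cls, session)
write.csv(data.frame(sweep_id = session$events$sweep_id, state = labels),
          "results/sweep_states.csv", row.names = FALSE)

ag <- state_agreement(session$states_truth, cls)
lab_t <- assign_sweep_states(session$states_truth, session)
labeled <- labels != "excluded"
cat(sprintf("state segmentation: %d intervals, %.1f%% of time labeled\n",
            nrow(cls), 100 * ag$labeled_fraction))
cat(sprintf("  agreement with ground truth over labeled time: %.1f%%\n",
            100 * ag$accuracy_labeled))
cat(sprintf("  sweeps: %d quiet, %d whisking, %d excluded; label accuracy %.1f%%\n",
            sum(labels == "quiet"), sum(labels == "whisking"),
            sum(labels == "excluded"),
            100 * mean(labels[labeled] == lab_t[labeled])))
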