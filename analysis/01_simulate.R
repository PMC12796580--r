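#!/usr/bin/env Rscript

# Step 1 - simulate one full-protocol session.
#
# Generates the default synthetic experiment: 30 sweeps of each of the
# three stimulation protocols (light only, air puff only, combined),
# repeated over two cycles in randomized block order, for a mixed
# population of S1 (tagged layer-6 corticothalamic cells, non-tagged
# cells across layers, two fast-spiking interneurons), POm and VPM
# units, together with the ground-truth whisking/quiet episode
# structure and the state-tracking LFP. Writes the session to
# results/session/ in the plain-CSV layout.

library(whiskloop)

seed <- 42L
out <- "results/session"

session <- generate_session(protocol_config(seed = seed),
                            default_unit_population(),
                            state_config())
write_session(session, out)

cat("simulated session\n")
print(session)
cat(sprintf("  conditions: %s\n",
            paste(names(table(session$events$condition)),
                  table(session$events$condition),
                  sep = "=", collapse = ", ")))
truth <- session$states_truth
cat(sprintf("  ground truth: %.1f s whisking / %.1f s quiet in %d bouts\n",
            sum((truth$end_ms - truth$start_ms)[truth$label == "whisking"]) / 1000,
            sum((truth$end_ms - truth$start_ms)[truth$label == "quiet"]) / 1000,
            nrow(truth)))
cat(sprintf("  total spikes: %d across %d units\n",
            sum(lengths(session$spikes)), length(session$spikes)))
cat(sprintf("written to %s/\n", out))
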