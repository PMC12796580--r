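#!/usr/bin/env Rscript

# Step 6 - averaged-PSTH report figures.
#
# One panel per (group, state): across-unit mean control and
# photoinactivation PSTHs with SEM bands, aligned to the
# deflection-at-whisker time.

library(whiskloop)

res <- run_pipeline(run_config(seed = 42L,
                               units = default_unit_population(),
                               group_by = "truth"))
figs <- make_report(res, "results/figures")
cat(sprintf("wrote %d figures to results/figures/\n", nrow(figs)))
print(figs[, c("group", "state")], row.names = FALSE)
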