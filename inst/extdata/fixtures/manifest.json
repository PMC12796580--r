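{
  "psth_worked_example": {
    "file": "psth_worked_example.json",
    "provenance": "PAPER",
    "description": "Sweep-normalization worked example: 100 spikes over 30 sweeps in a 1-s window give 100/30 = 3.33 spikes/s."
  },
  "interneuron_cases": {
    "file": "interneuron_cases.csv",
    "provenance": "PAPER",
    "description": "Fast-spiking interneuron criteria truth table, including strict-inequality boundary cases (asymmetry > 0.15, trough-to-peak < 0.3 ms, half-width < 0.2 ms)."
  },
  "layer_cases": {
    "file": "layer_cases.csv",
    "provenance": "PAPER",
    "description": "Cortical layer depth borders: L2/3 65-319, L4 320-539, L5 540-774, L6 > 775 um; boundary and out-of-range cases."
  },
  "anova_2x2_hand": {
    "file": "anova_2x2_hand.csv",
    "expected_file": "anova_2x2_hand_expected.json",
    "provenance": "DERIVED",
    "oracle": "Manual sums-of-squares arithmetic on the 4-subject 2x2 within-subject table: marginal-mean SS formulas for row/column/interaction and their subject-interaction error strata; F = effect MS / effect-by-subject MS; frozen to 12 significant digits.",
    "description": "4-subject, 2x2 both-within repeated-measures table with hand-computed SS decomposition and F values."
  },
  "onset_step": {
    "file": "onset_step.json",
    "provenance": "TRIVIAL",
    "description": "Noise-free PSTH: baseline 5 spikes/s (SD 0), step to 20 spikes/s from +6 ms for 10 bins; onset rule forces 6 ms."
  },
  "delta_example": {
    "file": "delta_example.json",
    "provenance": "PAPER",
    "description": "Photoinactivation rate decrease: control 7.09 spikes/s to 3.79 spikes/s gives a control-minus-light delta of 3.30 spikes/s."
  },
  "rout_contaminant": {
    "file": "rout_contaminant.csv",
    "provenance": "DERIVED",
    "oracle": "Direct evaluation of the sequential outlier test: with robust scale near 1, the point at 100 has a t-tail p-value below Q/n by many orders of magnitude while every other point's p-value exceeds its step-up threshold.",
    "description": "30 frozen unit-scale values plus one contaminant at 100; exactly the contaminant is an outlier at Q = 1%."
  },
  "bonferroni_cases": {
    "file": "bonferroni_cases.csv",
    "provenance": "TRIVIAL",
    "description": "Bonferroni multiplication cases including the cap at 1 and the m = 1 identity."
  }
}
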