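{
  "window_ms": [-200, 100],
  "bin_width_ms": 2,
  "baseline_rate": 5,
  "step_rate": 20,
  "step_at_ms": 6,
  "step_bins": 10,
  "expected_onset_ms": 6
}
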