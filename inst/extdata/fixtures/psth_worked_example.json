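{
  "n_spikes": 100,
  "n_sweeps": 30,
  "window_s": 1.0,
  "expected_rate": 3.3333333333333335
}
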