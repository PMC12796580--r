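peak_amplitude_asymmetry,trough_to_peak,half_width,expected
0.20,0.25,0.15,TRUE
0.20,0.35,0.15,FALSE
0.20,0.30,0.15,FALSE
0.15,0.25,0.15,FALSE
0.16,0.29,0.19,TRUE
0.20,0.25,0.20,FALSE
0.10,0.25,0.15,FALSE
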