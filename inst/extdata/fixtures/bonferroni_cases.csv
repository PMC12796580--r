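p,m,expected
0.02,2,0.04
0.8,3,1
0.3,1,0.3
0.001,10,0.01
1,5,1
0,4,0
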