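depth,expected
50,outside
65,L2/3
319,L2/3
320,L4
400,L4
539,L4
540,L5
774,L5
775,L6
800,L6
1200,L6
0,outside
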