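value
2.2872
-1.1968
-0.6943
-0.4123
-0.9707
-0.9473
0.7481
-0.117
0.1527
2.19
0.357
2.7168
2.2815
0.324
1.8961
0.4677
-0.8938
-0.3073
-0.0048
0.9882
0.8398
0.7053
1.306
-1.388
1.2729
0.1842
0.7523
0.5917
-0.9831
-0.2761
100
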