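subject,row,col,value
S1,A1,B1,10
S1,A1,B2,13
S1,A2,B1,21
S1,A2,B2,25
S2,A1,B1,12
S2,A1,B2,14
S2,A2,B1,19
S2,A2,B2,26
S3,A1,B1,9
S3,A1,B2,12
S3,A2,B1,22
S3,A2,B2,24
S4,A1,B1,11
S4,A1,B2,12
S4,A2,B1,20
S4,A2,B2,28
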