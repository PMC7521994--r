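left,right
6,1
7,2
8,3
9,4
10,5
11,NA
12,NA
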