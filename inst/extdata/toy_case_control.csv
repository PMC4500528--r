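id,D,X,g1,g2,g3
1,0,1,0,1,0
2,0,0,1,0,NA
3,0,0,0,0,1
4,0,1,2,1,0
5,0,0,0,0,0
6,0,1,1,NA,1
7,0,0,0,1,0
8,0,0,1,0,0
9,1,1,1,1,2
10,1,1,2,1,1
11,1,0,1,0,0
12,1,1,0,1,1
13,1,1,1,2,1
14,1,0,NA,1,0
15,1,1,2,2,1
16,1,1,1,1,0
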