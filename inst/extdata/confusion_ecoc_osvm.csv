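"",0,1,2,4,5,7,8,9
0,20,5,1,0,1,0,0,0
1,4,74,1,0,2,0,0,0
2,0,1,17,0,0,0,0,0
4,0,0,1,8,0,0,0,0
5,0,0,0,0,9,0,0,0
7,0,1,0,0,0,36,2,6
8,0,0,0,0,0,1,8,0
9,0,0,0,0,0,6,0,12
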