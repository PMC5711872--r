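"",0,1,2,4,5,7,8,9
0,18,5,2,1,1,0,0,0
1,3,75,1,2,0,0,0,0
2,0,5,13,0,0,0,0,0
4,0,0,0,9,0,0,0,0
5,2,0,0,0,7,0,0,0
7,2,4,0,0,1,27,6,5
8,0,0,0,0,0,0,9,0
9,0,1,0,0,0,5,0,12
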