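"pf_i","pf_j","angle_deg"
1,2,27.0583333333333
2,3,27.0583333333333
3,4,27.0583333333333
4,5,27.0583333333333
5,6,27.0583333333333
6,7,27.0583333333333
7,8,27.0583333333333
8,9,27.0583333333333
9,10,27.0583333333333
10,11,27.0583333333333
11,12,35.3
12,13,27.0583333333333
13,1,27.0583333333333
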