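age_start,weight
0,26.15
15,16.69
25,15.54
35,13.74
45,6.04
50,5.37
55,4.55
60,3.72
65,2.96
70,2.21
75,1.52
80,1.54
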