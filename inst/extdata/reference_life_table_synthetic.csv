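age_start,e_star
0,81.6
15,69.1
25,59.3
35,49.7
45,42.7
50,38.1
55,33.6
60,29.3
65,25
70,20.9
75,16.9
80,11.2
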