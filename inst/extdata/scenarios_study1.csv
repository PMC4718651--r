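scenario_id,study,predecessors,private_signal,reliability,prior_A
1,study1,EQ:A,a,0.666667,0.5
2,study1,EQ:A;EQ:A,a,0.666667,0.5
3,study1,EQ:A;EQ:B,a,0.666667,0.5
4,study1,EQ:A;EQ:A;EQ:A,a,0.666667,0.5
5,study1,EQ:A;EQ:B;EQ:A,a,0.666667,0.5
6,study1,EQ:A;EQ:A,b,0.666667,0.5
7,study1,EQ:A;EQ:B,b,0.666667,0.5
8,study1,EQ:A;EQ:A;EQ:A,b,0.666667,0.5
9,study1,EQ:A;EQ:B;EQ:B,b,0.666667,0.5
10,study1,EQ:A,b,0.666667,0.5
11,study1,EQ:A;EQ:B;EQ:B,a,0.666667,0.5
12,study1,EQ:A;EQ:B;EQ:A,b,0.666667,0.5
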