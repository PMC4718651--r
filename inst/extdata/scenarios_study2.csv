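scenario_id,study,predecessors,private_signal,reliability,prior_A
1,study2,EQ:A;EQ:B,a,0.666667,0.5
2,study2,EQ:A;EQ:B,b,0.666667,0.5
3,study2,EQ:A;EQ:A,b,0.666667,0.5
4,study2,EQ:A;EQ:A;EQ:A,b,0.666667,0.5
5,study2,HR:A;EQ:B,a,0.666667,0.5
6,study2,EQ:A;HR:B,b,0.666667,0.5
7,study2,HR:A;EQ:B,b,0.666667,0.5
8,study2,EQ:A;HR:B,a,0.666667,0.5
9,study2,HR:A;EQ:A,b,0.666667,0.5
10,study2,EQ:A;HR:A,b,0.666667,0.5
11,study2,HR:A;EQ:A;EQ:A,b,0.666667,0.5
12,study2,EQ:A;HR:A;EQ:A,b,0.666667,0.5
13,study2,EQ:A;EQ:A;HR:A,b,0.666667,0.5
14,study2,EQ:A,a,0.666667,0.5
15,study2,EQ:A;EQ:B;EQ:A,a,0.666667,0.5
16,study2,EQ:A;EQ:B;EQ:B,b,0.666667,0.5
17,study2,HR:A,a,0.666667,0.5
18,study2,HR:A;EQ:B;EQ:A,a,0.666667,0.5
19,study2,EQ:A;EQ:B;HR:A,a,0.666667,0.5
20,study2,EQ:A;HR:B;EQ:B,b,0.666667,0.5
21,study2,EQ:A;EQ:B;HR:B,b,0.666667,0.5
22,study2,EQ:A;HR:B;EQ:A,a,0.666667,0.5
23,study2,HR:A;EQ:B;EQ:B,b,0.666667,0.5
24,study2,EQ:A;EQ:A,a,0.666667,0.5
25,study2,EQ:A;EQ:A;EQ:A,a,0.666667,0.5
26,study2,HR:A;EQ:A,a,0.666667,0.5
27,study2,EQ:A;HR:A,a,0.666667,0.5
28,study2,HR:A;EQ:A;EQ:A,a,0.666667,0.5
29,study2,EQ:A;HR:A;EQ:A,a,0.666667,0.5
30,study2,EQ:A;EQ:A;HR:A,a,0.666667,0.5
31,study2,EQ:A,b,0.666667,0.5
32,study2,EQ:A;EQ:B;EQ:B,a,0.666667,0.5
33,study2,EQ:A;EQ:B;EQ:A,b,0.666667,0.5
34,study2,HR:A;EQ:B;EQ:B,a,0.666667,0.5
35,study2,EQ:A;HR:B;EQ:A,b,0.666667,0.5
36,study2,HR:A,b,0.666667,0.5
37,study2,EQ:A;HR:B;EQ:B,a,0.666667,0.5
38,study2,EQ:A;EQ:B;HR:B,a,0.666667,0.5
39,study2,HR:A;EQ:B;EQ:A,b,0.666667,0.5
40,study2,EQ:A;EQ:B;HR:A,b,0.666667,0.5
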