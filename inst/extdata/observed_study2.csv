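scenario_id,pct_choice,judgment
1,95.0,0.70
2,92.5,0.66
3,75.0,0.60
4,75.0,0.66
5,95.0,0.72
6,92.5,0.68
7,87.5,0.61
8,82.5,0.64
9,82.5,0.67
10,82.5,0.65
11,87.5,0.70
12,87.5,0.72
13,85.0,0.71
14,97.5,0.80
15,95.0,0.77
16,97.5,0.75
17,97.5,0.83
18,95.0,0.79
19,97.5,0.79
20,95.0,0.76
21,97.5,0.77
22,90.0,0.72
23,82.5,0.63
24,100.0,0.84
25,97.5,0.86
26,100.0,0.87
27,100.0,0.85
28,100.0,0.89
29,100.0,0.88
30,100.0,0.88
31,70.0,0.62
32,40.0,0.63
33,60.0,0.66
34,75.0,0.68
35,60.0,0.69
36,37.5,0.62
37,40.0,0.63
38,30.0,0.66
39,47.5,0.66
40,37.5,0.68
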