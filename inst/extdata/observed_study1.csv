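scenario_id,pct_choice,judgment
1,91.3,0.66
2,90.0,0.74
3,91.1,0.62
4,85.0,0.75
5,85.0,0.69
6,71.3,0.54
7,95.0,0.66
8,79.7,0.65
9,93.8,0.74
10,90.0,0.60
11,65.0,0.60
12,84.8,0.58
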