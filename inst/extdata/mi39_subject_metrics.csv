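Subject,ER,RT,S0,S1,S2,Sp0,Sp1,Sp2
1,0.17667,0.82333,0.83000,0.81500,0.82500,0.82000,0.82750,0.82250
2,0.18625,0.81375,0.81375,0.79500,0.83250,0.81375,0.82312,0.80437
3,0.17542,0.82458,0.85125,0.79000,0.83250,0.81125,0.84188,0.82063
4,0.19145,0.80855,0.81923,0.81410,0.79231,0.80321,0.80577,0.81667
5,0.20875,0.79125,0.77750,0.79125,0.80500,0.79812,0.79125,0.78437
6,0.15792,0.84208,0.86500,0.81875,0.84250,0.83063,0.85375,0.84187
7,0.18417,0.81583,0.83500,0.79875,0.81375,0.80625,0.82438,0.81687
8,0.18333,0.81667,0.82125,0.80625,0.82250,0.81437,0.82188,0.81375
9,0.17125,0.82875,0.82875,0.83625,0.82125,0.82875,0.82500,0.83250
10,0.16458,0.83542,0.86375,0.84375,0.79875,0.82125,0.83125,0.85375
11,0.18803,0.81197,0.80641,0.81154,0.81795,0.81474,0.81218,0.80897
12,0.15500,0.84500,0.83125,0.84000,0.86375,0.85187,0.84750,0.83562
13,0.19542,0.80458,0.83125,0.78250,0.80000,0.79125,0.81563,0.80688
14,0.15792,0.84208,0.85000,0.82625,0.85000,0.83813,0.85000,0.83813
15,0.19167,0.80833,0.80625,0.79875,0.82000,0.80937,0.81312,0.80250
16,0.19458,0.80542,0.82500,0.76875,0.82250,0.79563,0.82375,0.79688
17,0.16292,0.83708,0.85000,0.83500,0.82625,0.83063,0.83813,0.84250
18,0.17137,0.82863,0.84615,0.81154,0.82821,0.81987,0.83718,0.82885
19,0.15875,0.84125,0.84000,0.83250,0.85125,0.84187,0.84562,0.83625
20,0.18250,0.81750,0.81500,0.80375,0.83375,0.81875,0.82438,0.80937
21,0.31250,0.68750,0.65625,0.68625,0.72000,0.70312,0.68812,0.67125
22,0.16708,0.83292,0.86250,0.82125,0.81500,0.81812,0.83875,0.84188
23,0.18917,0.81083,0.82375,0.81625,0.79250,0.80437,0.80813,0.82000
24,0.16958,0.83042,0.84250,0.81500,0.83375,0.82438,0.83813,0.82875
25,0.17500,0.82500,0.84079,0.83947,0.79474,0.81711,0.81776,0.84013
26,0.19583,0.80417,0.80750,0.80250,0.80250,0.80250,0.80500,0.80500
27,0.16500,0.83500,0.83000,0.82750,0.84750,0.83750,0.83875,0.82875
28,0.20083,0.79917,0.78500,0.79625,0.81625,0.80625,0.80063,0.79062
29,0.18947,0.81053,0.83421,0.79474,0.80263,0.79868,0.81842,0.81447
30,0.16083,0.83917,0.85875,0.83250,0.82625,0.82937,0.84250,0.84563
31,0.17875,0.82125,0.83375,0.80625,0.82375,0.81500,0.82875,0.82000
32,0.19083,0.80917,0.82125,0.81125,0.79500,0.80312,0.80812,0.81625
33,0.19333,0.80667,0.82125,0.79750,0.80125,0.79937,0.81125,0.80937
34,0.18917,0.81083,0.80250,0.82000,0.81000,0.81500,0.80625,0.81125
35,0.16333,0.83667,0.86500,0.82750,0.81750,0.82250,0.84125,0.84625
36,0.16833,0.83167,0.83250,0.82250,0.84000,0.83125,0.83625,0.82750
37,0.18833,0.81167,0.83125,0.81000,0.79375,0.80188,0.81250,0.82063
38,0.17000,0.83000,0.81125,0.86750,0.81125,0.83937,0.81125,0.83938
39,0.19083,0.80917,0.82125,0.80375,0.80250,0.80313,0.81187,0.81250
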