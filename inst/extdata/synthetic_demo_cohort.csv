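"id","unmet_financial","unmet_nonfinancial","income","ln_income","age","shi","education","chronic","urban"
1,0,0,17775.48,9.785632,59.7,1,"Primary school",1,0
2,0,0,11789.59,9.375057,59.5,1,"Middle school",0,1
3,0,1,7432.54,8.913757,50.9,1,"Illiterate",0,1
4,0,1,6834.22,8.829844,61.4,1,"Illiterate",1,0
5,0,0,20465.15,9.926528,55.3,1,"Middle school",0,1
6,0,1,22785.6,10.033928,62.1,1,"Primary school",1,0
7,0,0,12428.13,9.427798,52.4,1,"Primary school",1,0
8,0,1,7320.05,8.898509,52.9,1,"Primary school",1,0
9,0,0,3041.48,8.020428,58.9,1,"Primary school",0,0
10,0,0,3304.1,8.103222,69.1,1,"Illiterate",1,0
11,1,0,2126.98,7.662928,55.5,1,"Middle school",1,0
12,0,0,11791.5,9.375219,63.9,1,"Primary school",1,1
13,0,0,15768.22,9.665815,56.2,1,"Primary school",1,0
14,0,0,10243.69,9.234515,63.2,1,"Primary school",1,1
15,1,0,590.26,6.382256,82.2,1,"Illiterate",0,0
16,1,1,7197.66,8.88165,55.3,1,"Primary school",1,0
17,1,0,3850.85,8.256309,52.6,1,"Illiterate",0,1
18,0,1,11653.61,9.363457,67.7,1,"Primary school",1,1
19,0,0,2241.98,7.715561,67.7,1,"High school and above",0,0
20,0,0,1621.04,7.39144,62.2,1,"Illiterate",1,0
21,0,0,20170.6,9.912031,67.2,1,"Middle school",1,1
22,1,0,10431.26,9.252658,51,1,"Primary school",0,0
23,1,0,18660.21,9.834202,54.6,1,"Middle school",1,0
24,0,0,6833.65,8.829761,79.8,1,"Primary school",1,0
25,0,1,11133.13,9.31777,70.9,0,"High school and above",1,0
26,0,0,2356.84,7.765501,71.5,1,"Primary school",0,0
27,0,0,7371.97,8.905576,79.6,1,"Illiterate",0,0
28,0,0,14013.25,9.54783,63.8,1,"Middle school",1,0
29,0,0,1564.66,7.356063,73.3,1,"Illiterate",1,0
30,0,1,7423.91,8.912596,73.1,1,"Middle school",0,0
31,0,1,2561.03,7.848555,53.7,1,"Illiterate",1,0
32,1,0,6246.22,8.739892,63,1,"Primary school",1,0
33,0,1,5408.76,8.59596,86.2,1,"Middle school",0,0
34,0,0,21234.86,9.963447,73.7,1,"Primary school",1,0
35,0,1,5436.1,8.601001,56.3,1,"Middle school",0,0
36,0,0,11066.48,9.311766,34.8,1,"Middle school",0,1
37,1,0,10613.32,9.269959,65.9,1,"Primary school",0,0
38,0,0,5478.52,8.608773,60.7,1,"Primary school",0,1
39,0,1,5132.68,8.543578,56.9,1,"Illiterate",1,0
40,0,0,11415.09,9.342779,65.5,1,"Primary school",0,1
41,0,0,4032.05,8.302278,80.4,1,"High school and above",0,0
42,0,1,8072.73,8.996371,63.1,1,"Middle school",0,0
43,0,0,12043.74,9.396383,62.6,1,"Primary school",0,1
44,0,0,39271.52,10.57828,76,1,"Primary school",0,1
45,1,1,3110.41,8.042831,60.6,1,"Primary school",0,0
46,0,1,8994.34,9.104462,57,1,"Illiterate",1,0
47,0,0,10543.32,9.263343,64.1,1,"Primary school",0,0
48,1,0,13829.05,9.534599,46.2,1,"Primary school",1,1
49,0,0,13510.12,9.511268,74.1,1,"Middle school",1,0
50,0,1,38267.68,10.552387,82,1,"High school and above",1,0
51,0,1,5199.77,8.556562,60.1,1,"Middle school",0,1
52,0,0,4391.52,8.387658,72.6,1,"Primary school",0,0
53,0,0,4830.21,8.482852,59.1,1,"Primary school",1,0
54,0,0,3561.64,8.178257,66,1,"Primary school",1,0
55,0,0,4699.83,8.455494,67.5,1,"Primary school",1,0
56,0,0,2573.73,7.8535,75.4,1,"Illiterate",1,1
57,0,0,16587.34,9.716455,74,1,"Illiterate",1,0
58,1,0,6692.55,8.8089,64.9,1,"Illiterate",0,0
59,0,1,18039.57,9.800378,68.9,1,"Illiterate",0,0
60,0,0,7894.55,8.974055,59.6,1,"Primary school",1,0
61,0,0,28979.9,10.274392,68.2,1,"Illiterate",0,1
62,0,0,16125.51,9.68822,64.7,1,"High school and above",0,0
63,0,0,12465.2,9.430776,68.9,1,"Primary school",1,1
64,0,1,9322.6,9.140304,56.6,1,"Primary school",0,1
65,1,0,30233.88,10.316752,58,1,"High school and above",0,0
66,1,1,7309.2,8.897026,70.3,1,"Primary school",1,1
67,0,0,1641.88,7.404206,74.4,1,"Primary school",1,0
68,0,1,14352.96,9.571781,59,1,"Illiterate",0,1
69,1,0,12008.38,9.393443,56.3,1,"Middle school",0,0
70,0,0,1487.65,7.305625,69.6,1,"Primary school",1,0
71,0,0,20031.37,9.905105,56.5,1,"High school and above",1,1
72,0,0,3082.29,8.033752,54.4,1,"Middle school",1,0
73,0,0,10267.03,9.23679,68.1,1,"Middle school",1,0
74,0,0,8606,9.060331,73.1,1,"Illiterate",1,0
75,0,0,9479.89,9.157033,75.1,1,"Middle school",1,0
76,1,0,6309.38,8.749951,68.9,1,"Middle school",1,0
77,0,0,25261.38,10.137072,73.7,1,"Illiterate",0,1
78,0,0,13999.49,9.546848,67.1,1,"Primary school",1,0
79,1,0,3529.51,8.169198,85.8,1,"Illiterate",1,0
80,0,0,8205.39,9.012668,45.9,1,"Primary school",1,0
81,0,0,2997.2,8.005767,64.3,1,"Illiterate",1,0
82,0,0,17916.68,9.793543,66.7,1,"High school and above",1,1
83,0,0,16174.19,9.691234,54.9,1,"Primary school",0,1
84,1,0,1990.16,7.596473,66.7,1,"Illiterate",1,1
85,0,0,9127.5,9.119157,72.6,1,"Middle school",0,1
86,0,0,19693.81,9.88811,52.5,1,"Primary school",1,0
87,0,0,7000.93,8.853941,56.2,1,"Illiterate",1,1
88,1,0,6606.77,8.796002,64.7,1,"Illiterate",1,0
89,0,0,6629.27,8.799401,71.7,1,"Primary school",1,0
90,0,1,15573.04,9.653361,66.4,1,"Primary school",0,0
91,0,1,3035.31,8.018398,57.7,1,"Illiterate",0,0
92,1,0,5340.19,8.583204,68.9,1,"Primary school",0,0
93,0,0,4611.14,8.436447,58.4,1,"Illiterate",1,1
94,0,0,14043.99,9.550021,36.5,1,"Illiterate",0,1
95,0,0,12557.51,9.438154,68.7,1,"Middle school",1,1
96,1,0,1552.03,7.347963,68.8,1,"Primary school",1,0
97,0,0,3188.62,8.067657,70.8,1,"Primary school",0,0
98,0,0,3154.55,8.056918,69.2,0,"Primary school",1,1
99,0,0,7912.45,8.976319,57.5,1,"Illiterate",1,1
100,0,0,20357.76,9.921267,72.2,1,"High school and above",0,0
101,0,0,47426.17,10.766951,54.8,1,"High school and above",0,0
102,0,0,11523.07,9.352193,76.8,1,"Middle school",1,1
103,0,0,18667.38,9.834586,63.4,1,"Middle school",0,0
104,0,0,8960.14,9.100653,62.3,1,"Middle school",0,0
105,0,0,2944.81,7.988139,64.6,1,"Illiterate",1,0
106,0,0,10932.42,9.299579,65,1,"Primary school",1,0
107,0,0,6907.15,8.840457,62.5,1,"Primary school",1,0
108,0,0,20410.94,9.923875,66.3,1,"High school and above",0,0
109,0,0,5170.04,8.550829,61.2,1,"High school and above",1,0
110,0,0,3261.02,8.090102,70,1,"Illiterate",1,0
111,1,0,2879.3,7.96565,77.1,1,"Primary school",1,0
112,0,0,19927.37,9.8999,68.4,1,"Primary school",0,0
113,0,0,4624.85,8.439415,61.7,1,"Illiterate",0,0
114,0,0,7918.04,8.977025,59.6,1,"Primary school",1,0
115,0,0,4914.87,8.500224,63.4,0,"Primary school",1,1
116,0,0,1873.77,7.536241,65.7,1,"Illiterate",1,0
117,0,1,37191.46,10.523861,60.7,1,"Middle school",0,1
118,0,0,12381.21,9.424016,57.7,1,"Primary school",1,1
119,0,0,6556.21,8.78832,64.1,1,"Illiterate",1,1
120,0,1,16742.7,9.725777,53.6,1,"Middle school",0,1
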