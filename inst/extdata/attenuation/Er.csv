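energy_keV,mu_over_rho_cm2_g
3,1667.86
3.19219,1438.07
3.3967,1239.1
3.6143,1067.01
3.84585,918.039
4.09223,789.394
4.3544,678.327
4.63336,582.579
4.93019,500.137
5.24604,429.203
5.58212,368.201
5.93973,315.765
6.32025,270.698
6.72516,231.977
7.156,198.751
7.61444,170.247
8.357,143.322
8.359,315.957
9.263,270.218
9.265,327.712
9.75,319.268
9.752,328.459
10.3867,294.814
11.0521,251.727
11.7601,214.808
12.5135,183.161
13.3152,156.071
14.1682,132.922
15.0759,113.153
16.0417,96.2815
17.0694,81.8843
18.163,69.6046
19.3266,59.1395
20.5647,50.2273
21.8822,42.6493
23.284,36.2087
24.7757,30.7364
26.3629,26.0882
28.0518,22.1324
29.8489,18.7763
31.7612,15.9314
33.7959,13.52
35.9611,11.4762
38.2649,9.74166
40.7163,8.27169
43.3247,7.02353
46.1003,5.96538
49.0536,5.0706
52.1962,4.31378
55.5401,3.67351
57.499,3.39002
57.501,15.0849
59.0982,14.2098
62.8843,12.1285
66.9129,10.3364
71.1997,8.80675
75.761,7.50189
80.6146,6.38802
85.7791,5.43363
91.2744,4.62263
97.1218,3.93368
103.344,3.34858
109.964,2.85181
117.009,2.42748
124.505,2.06295
132.482,1.75591
140.969,1.49716
150,1.27897
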