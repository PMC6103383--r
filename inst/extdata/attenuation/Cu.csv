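energy_keV,mu_over_rho_cm2_g
3,764.537
3.19219,649.003
3.3967,550.678
3.6143,467.046
3.84585,395.853
4.09223,335.276
4.3544,283.896
4.63336,240.329
4.93019,203.356
5.24604,172.015
5.58212,145.482
5.93973,123.024
6.32025,104.021
6.72516,87.945
7.156,74.3473
7.61444,62.8483
8.10225,53.1259
8.978,42.7572
8.98,274.008
9.76133,232.082
10.3867,197.789
11.0521,168.354
11.7601,143.103
12.5135,121.384
13.3152,102.871
14.1682,87.1048
15.0759,73.6912
16.0417,62.2898
17.0694,52.608
18.163,44.3887
19.3266,37.4084
20.5647,31.5078
21.8822,26.5235
23.284,22.3162
24.7757,18.7673
26.3629,15.7763
28.0518,13.2516
29.8489,11.1282
31.7612,9.34473
33.7959,7.84742
35.9611,6.59097
38.2649,5.53713
40.7163,4.64873
43.3247,3.90449
46.1003,3.28273
49.0536,2.76335
52.1962,2.32952
55.5401,1.96715
59.0982,1.66448
62.8843,1.41164
66.9129,1.20042
71.1997,1.02392
75.761,0.876395
80.6146,0.753042
85.7791,0.649848
91.2744,0.563462
97.1218,0.491089
103.344,0.430395
109.964,0.379434
117.009,0.336581
124.505,0.300485
132.482,0.270016
140.969,0.244234
150,0.222356
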