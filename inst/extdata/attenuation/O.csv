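energy_keV,mu_over_rho_cm2_g
3,210.442
3.19219,175.541
3.3967,146.351
3.6143,121.953
3.84585,101.572
4.09223,84.5576
4.3544,70.361
4.63336,58.5228
4.93019,48.6569
5.24604,40.4393
5.58212,33.5986
5.93973,27.9072
6.32025,23.1746
6.72516,19.2414
7.156,15.9743
7.61444,13.262
8.10225,11.0113
8.62131,9.14468
9.17363,7.59683
9.76133,6.31473
10.3867,5.25003
11.0521,4.36848
11.7601,3.64055
12.5135,3.03955
13.3152,2.54335
14.1682,2.13365
15.0759,1.79536
16.0417,1.51598
17.0694,1.28523
18.163,1.09459
19.3266,0.937039
20.5647,0.806783
21.8822,0.699037
23.284,0.609856
24.7757,0.535982
26.3629,0.474729
28.0518,0.423561
29.8489,0.381055
31.7612,0.345746
33.7959,0.316347
35.9611,0.291798
38.2649,0.271233
40.7163,0.253937
43.3247,0.239326
46.1003,0.226917
49.0536,0.216316
52.1962,0.207196
55.5401,0.199291
59.0982,0.192381
62.8843,0.186285
66.9129,0.180853
71.1997,0.175964
75.761,0.171517
80.6146,0.167429
85.7791,0.163633
91.2744,0.160073
97.1218,0.156703
103.344,0.153487
109.964,0.150394
117.009,0.1474
124.505,0.144485
132.482,0.141634
140.969,0.138835
150,0.136077
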