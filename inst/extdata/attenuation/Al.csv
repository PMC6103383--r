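energy_keV,mu_over_rho_cm2_g
3,787.275
3.19219,665.428
3.3967,561.517
3.6143,473.456
3.84585,398.889
4.09223,335.799
4.3544,282.466
4.63336,237.419
4.93019,199.402
5.24604,167.344
5.58212,140.334
5.93973,117.596
6.32025,98.4702
6.72516,82.3959
7.156,68.8753
7.61444,57.5438
8.10225,48.0548
8.62131,40.1135
9.17363,33.4459
9.76133,27.8584
10.3867,23.2017
11.0521,19.3222
11.7601,16.0915
12.5135,13.4019
13.3152,11.1637
14.1682,9.30176
15.0759,7.75333
16.0417,6.46605
17.0694,5.3962
18.163,4.50731
19.3266,3.76897
20.5647,3.15583
21.8822,2.64677
23.284,2.22421
24.7757,1.87349
26.3629,1.58242
28.0518,1.34075
29.8489,1.14024
31.7612,0.973876
33.7959,0.835815
35.9611,0.721198
38.2649,0.625995
40.7163,0.546865
43.3247,0.481037
46.1003,0.426217
49.0536,0.380501
52.1962,0.342314
55.5401,0.310351
59.0982,0.283532
62.8843,0.260963
66.9129,0.241902
71.1997,0.225739
75.761,0.211967
80.6146,0.200167
85.7791,0.189994
91.2744,0.181162
97.1218,0.173435
103.344,0.166618
109.964,0.160552
117.009,0.155103
124.505,0.150163
132.482,0.145644
140.969,0.141471
150,0.137584
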