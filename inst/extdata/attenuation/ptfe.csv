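energy_keV,mu_over_rho_cm2_g
3,234.706
3.19219,196.126
3.3967,163.797
3.6143,136.723
3.84585,114.065
4.09223,95.1122
4.3544,79.2698
4.63336,66.0352
4.93019,54.9857
5.24604,45.7659
5.58212,38.0761
5.93973,31.6673
6.32025,26.3297
6.72516,21.8866
7.156,18.1901
7.61444,15.1165
8.10225,12.5621
8.62131,10.4402
9.17363,8.67603
9.76133,7.21128
10.3867,5.9981
11.0521,4.99351
11.7601,4.16186
12.5135,3.47351
13.3152,2.90287
14.1682,2.43043
15.0759,2.04004
16.0417,1.71742
17.0694,1.45078
18.163,1.23039
19.3266,1.04817
20.5647,0.897475
21.8822,0.772803
23.284,0.669609
24.7757,0.584142
26.3629,0.513302
28.0518,0.454019
29.8489,0.404827
31.7612,0.364051
33.7959,0.33018
35.9611,0.301975
38.2649,0.278419
40.7163,0.25868
43.3247,0.242072
46.1003,0.228034
49.0536,0.216104
52.1962,0.205905
55.5401,0.197123
59.0982,0.189504
62.8843,0.182837
66.9129,0.176948
71.1997,0.171697
75.761,0.166965
80.6146,0.162656
85.7791,0.158693
91.2744,0.15501
97.1218,0.151555
103.344,0.148283
109.964,0.145161
117.009,0.142159
124.505,0.139254
132.482,0.136428
140.969,0.133666
150,0.130956
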