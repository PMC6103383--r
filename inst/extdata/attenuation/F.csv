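energy_keV,mu_over_rho_cm2_g
3,281.472
3.19219,235.357
3.3967,196.685
3.6143,164.275
3.84585,137.131
4.09223,114.41
4.3544,95.4034
4.63336,79.515
4.93019,66.2408
5.24604,55.1575
5.58212,45.909
5.93973,38.1961
6.32025,31.7677
6.72516,26.4129
7.156,21.955
7.61444,18.2459
8.10225,15.1615
8.62131,12.5981
9.17363,10.466
9.76133,8.69526
10.3867,7.2278
11.0521,6.01205
11.7601,5.0051
12.5135,4.17131
13.3152,3.47975
14.1682,2.90697
15.0759,2.43358
16.0417,2.04233
17.0694,1.71895
18.163,1.45164
19.3266,1.23066
20.5647,1.04792
21.8822,0.896777
23.284,0.771712
24.7757,0.668177
26.3629,0.582414
28.0518,0.510684
29.8489,0.451222
31.7612,0.401998
33.7959,0.361175
35.9611,0.327246
38.2649,0.298978
40.7163,0.275356
43.3247,0.255549
46.1003,0.238874
49.0536,0.22477
52.1962,0.212776
55.5401,0.202515
59.0982,0.193675
62.8843,0.186
66.9129,0.179281
71.1997,0.173344
75.761,0.168047
80.6146,0.163274
85.7791,0.158928
91.2744,0.154931
97.1218,0.151218
103.344,0.147736
109.964,0.144443
117.009,0.141302
124.505,0.138286
132.482,0.135372
140.969,0.13254
150,0.129776
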