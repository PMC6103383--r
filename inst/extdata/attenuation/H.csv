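energy_keV,mu_over_rho_cm2_g
3,0.51978
3.19219,0.505014
3.3967,0.491881
3.6143,0.480192
3.84585,0.469778
4.09223,0.460491
4.3544,0.452199
4.63336,0.444784
4.93019,0.438142
5.24604,0.43218
5.58212,0.426817
5.93973,0.421979
6.32025,0.417601
6.72516,0.413626
7.156,0.410001
7.61444,0.406681
8.10225,0.403626
8.62131,0.400797
9.17363,0.398163
9.76133,0.395694
10.3867,0.393363
11.0521,0.391148
11.7601,0.389025
12.5135,0.386977
13.3152,0.384986
14.1682,0.383035
15.0759,0.381111
16.0417,0.3792
17.0694,0.37729
18.163,0.37537
19.3266,0.373429
20.5647,0.37146
21.8822,0.369452
23.284,0.367398
24.7757,0.36529
26.3629,0.363122
28.0518,0.360887
29.8489,0.358579
31.7612,0.356193
33.7959,0.353724
35.9611,0.351168
38.2649,0.34852
40.7163,0.345777
43.3247,0.342936
46.1003,0.339994
49.0536,0.336948
52.1962,0.333798
55.5401,0.330541
59.0982,0.327177
62.8843,0.323707
66.9129,0.32013
71.1997,0.316447
75.761,0.312659
80.6146,0.30877
85.7791,0.304781
91.2744,0.300695
97.1218,0.296517
103.344,0.292251
109.964,0.2879
117.009,0.283471
124.505,0.278969
132.482,0.2744
140.969,0.269771
150,0.265087
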