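energy_keV,mu_over_rho_cm2_g
3,86.7666
3.19219,72.0208
3.3967,59.7577
3.6143,49.5647
3.84585,41.0971
4.09223,34.0665
4.3544,28.232
4.63336,23.3926
4.93019,19.3807
5.24604,16.0563
5.58212,13.297
5.93973,11.0137
6.32025,9.12679
6.72516,7.56781
7.156,6.28011
7.61444,5.21671
8.10225,4.33873
8.62131,3.61397
9.17363,3.01352
9.76133,2.51683
10.3867,2.108
11.0521,1.77144
11.7601,1.49431
12.5135,1.26604
13.3152,1.07796
14.1682,0.922932
15.0759,0.795078
16.0417,0.689576
17.0694,0.602455
18.163,0.530453
19.3266,0.470886
20.5647,0.421546
21.8822,0.38062
23.284,0.346614
24.7757,0.318301
26.3629,0.29467
28.0518,0.274764
29.8489,0.258059
31.7612,0.244008
33.7959,0.23213
35.9611,0.222029
38.2649,0.213383
40.7163,0.205925
43.3247,0.199438
46.1003,0.193743
49.0536,0.188693
52.1962,0.184168
55.5401,0.180067
59.0982,0.17631
62.8843,0.17283
66.9129,0.16957
71.1997,0.166486
75.761,0.163541
80.6146,0.160704
85.7791,0.157951
91.2744,0.155263
97.1218,0.152621
103.344,0.150015
109.964,0.147434
117.009,0.14487
124.505,0.142316
132.482,0.13977
140.969,0.137228
150,0.134688
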