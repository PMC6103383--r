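energy_keV,mu_over_rho_cm2_g
3,186.95
3.19219,155.953
3.3967,130.029
3.6143,108.36
3.84585,90.2584
4.09223,75.1465
4.3544,62.5377
4.63336,52.0235
4.93019,43.2609
5.24604,35.9622
5.58212,29.8864
5.93973,24.8314
6.32025,20.6279
6.72516,17.1344
7.156,14.2326
7.61444,11.8234
8.10225,9.82425
8.62131,8.16618
9.17363,6.79125
9.76133,5.65235
10.3867,4.70654
11.0521,3.92339
11.7601,3.27668
12.5135,2.74271
13.3152,2.30181
14.1682,1.93775
15.0759,1.63709
16.0417,1.38877
17.0694,1.18363
18.163,1.0141
19.3266,0.873967
20.5647,0.758067
21.8822,0.662154
23.284,0.582723
24.7757,0.51688
26.3629,0.46224
28.0518,0.416547
29.8489,0.37854
31.7612,0.346915
33.7959,0.32053
35.9611,0.298442
38.2649,0.279882
40.7163,0.264215
43.3247,0.250921
46.1003,0.239571
49.0536,0.229815
52.1962,0.221364
55.5401,0.213979
59.0982,0.207466
62.8843,0.201663
66.9129,0.196439
71.1997,0.191685
75.761,0.187312
80.6146,0.183246
85.7791,0.179428
91.2744,0.175809
97.1218,0.172349
103.344,0.169015
109.964,0.165782
117.009,0.162627
124.505,0.159535
132.482,0.156492
140.969,0.153487
150,0.150514
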