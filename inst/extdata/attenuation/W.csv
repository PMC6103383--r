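energy_keV,mu_over_rho_cm2_g
3,2067.65
3.19219,1787.99
3.3967,1544.76
3.6143,1333.32
3.84585,1149.23
4.09223,989.735
4.3544,851.924
4.63336,732.853
4.93019,629.92
5.24604,541.142
5.58212,464.604
5.93973,398.717
6.32025,342.059
6.72516,293.365
7.156,251.532
7.61444,215.606
8.10225,184.763
8.62131,158.294
9.17363,135.545
10.206,109.004
10.208,238.721
11.543,187.584
11.545,232.519
12.099,224.472
12.101,236.383
13.3152,193.559
14.1682,165.305
15.0759,141.088
16.0417,120.322
17.0694,102.559
18.163,87.3776
19.3266,74.4096
20.5647,63.3377
21.8822,53.8871
23.284,45.8303
24.7757,38.9639
26.3629,33.1189
28.0518,28.1285
29.8489,23.8863
31.7612,20.2851
33.7959,17.2282
35.9611,14.6338
38.2649,12.4321
40.7163,10.5638
43.3247,8.97853
46.1003,7.63225
49.0536,6.49014
52.1962,5.52111
55.5401,4.69764
59.0982,4.00039
62.8843,3.41001
66.9129,2.90998
69.524,2.65982
69.526,11.1663
71.1997,10.6077
75.761,9.06381
80.6146,7.73203
85.7791,6.59953
91.2744,5.63006
97.1218,4.79732
103.344,4.08898
109.964,3.48656
117.009,2.97431
124.505,2.5388
132.482,2.16858
140.969,1.85234
150,1.57978
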