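energy_keV,mu_over_rho_cm2_g
3,105.324
3.19219,87.5917
3.3967,72.8134
3.6143,60.5042
3.84585,50.2573
4.09223,41.7318
4.3544,34.6423
4.63336,28.75
4.93019,23.8554
5.24604,19.7916
5.58212,16.4147
5.93973,13.6146
6.32025,11.295
6.72516,9.37419
7.156,7.78414
7.61444,6.46834
8.10225,5.37981
8.62131,4.47959
9.17363,3.73349
9.76133,3.11597
10.3867,2.60591
11.0521,2.18504
11.7601,1.83808
12.5135,1.55201
13.3152,1.3161
14.1682,1.1215
15.0759,0.96091
16.0417,0.828338
17.0694,0.718835
18.163,0.628329
19.3266,0.553465
20.5647,0.491481
21.8822,0.440102
23.284,0.397455
24.7757,0.361997
26.3629,0.332456
28.0518,0.30763
29.8489,0.286854
31.7612,0.269438
33.7959,0.254774
35.9611,0.242365
38.2649,0.231802
40.7163,0.222749
43.3247,0.214931
46.1003,0.208121
49.0536,0.202135
52.1962,0.196818
55.5401,0.192047
59.0982,0.187716
62.8843,0.183742
66.9129,0.180055
71.1997,0.176597
75.761,0.173322
80.6146,0.170191
85.7791,0.167172
91.2744,0.164242
97.1218,0.161378
103.344,0.158564
109.964,0.155788
117.009,0.153039
124.505,0.15031
132.482,0.147594
140.969,0.144887
150,0.142187
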