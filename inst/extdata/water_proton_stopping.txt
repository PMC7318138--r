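# Unrestricted electronic stopping power of liquid water for protons.
# ICRU49/PSTAR-consistent values, mean excitation potential I = 78 eV
# (ICRU90 convention); tabulated as keV/um (mass stopping power in
# MeV cm2/g times 1 g/cm3, converted: 1 MeV cm2/g = 0.1 keV/um).
# columns: energy_MeV  sw_keV_um
0.01  30
0.015  36
0.02  42
0.03  52
0.04  60
0.05  67
0.06  73
0.07  78
0.08  81.6
0.09  81.2
0.1  80.5
0.12  78
0.15  74
0.2  68
0.25  63
0.3  58.5
0.4  51
0.5  42.8
0.6  38.2
0.7  34.7
0.8  31.8
0.9  28.8
1  26.08
1.1015  24.381
1.21331  22.7763
1.33646  21.263
1.47211  19.8376
1.62153  18.4966
1.78612  17.2365
1.96741  16.0536
2  15.86
2.16711  14.9449
2.38707  13.9073
2.62937  12.9367
2.89625  12.0289
3.19022  11.1802
3.51404  10.387
3.87072  9.64575
4.2636  8.95339
4.69636  8.30686
5  7.911
5.17305  7.70339
5.69812  7.14116
6.27649  6.6178
6.91357  6.13087
7.6153  5.67806
8.38827  5.25714
9.23969  4.86607
10  4.567
10.1775  4.50289
11.2106  4.16576
12.3485  3.85312
13.6018  3.56341
14.9825  3.29511
15  3.292
16.5032  3.04688
18.1783  2.81718
20  2.607
20.0234  2.60452
22.0558  2.4078
24.2945  2.22602
26.7605  2.05811
29.4767  1.90308
32.4686  1.75999
35.7642  1.62796
39.3944  1.50618
43.3929  1.3939
47.7974  1.29041
50  1.245
52.6489  1.19506
57.9929  1.10727
63.8792  1.02646
70.3631  0.952112
77.505  0.883741
85.3719  0.820892
94.0373  0.763146
100  0.7289
103.582  0.710118
114.096  0.661443
125.677  0.616793
138.433  0.575858
152.484  0.53835
167.962  0.504005
185.01  0.472584
203.789  0.443859
224.474  0.417625
247.258  0.393692
250  0.3911
272.355  0.37187
300  0.352
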