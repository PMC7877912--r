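r_nm	g
0.05	0
0.15	0
0.25	0
0.35	0
0.45	0
0.55	0
0.65	0
0.75	0
0.85	0
0.95	0
1.05	0
1.15	0
1.25	0
1.35	0
1.45	0
1.55	0
1.65	0
1.75	0
1.85	0
1.95	0
2.05	0
2.15	0
2.25	0
2.35	0
2.45	0
2.55	0
2.65	0.00714
2.75	0.10743
2.85	0.60696
2.95	1.66379
3.05	2.89085
3.15	3.76663
3.25	3.92493
3.35	3.59044
3.45	3.18981
3.55	2.72093
3.65	2.3322
3.75	1.92059
3.85	1.66309
3.95	1.42855
4.05	1.25338
4.15	1.11886
4.25	0.99047
4.35	0.96428
4.45	0.87179
4.55	0.84261
4.65	0.80653
4.75	0.80916
4.85	0.79277
4.95	0.81367
5.05	0.85178
5.15	0.87027
5.25	0.92406
5.35	0.95415
5.45	0.99578
5.55	1.06753
5.65	1.10266
5.75	1.15157
5.85	1.16676
5.95	1.19163
6.05	1.22067
6.15	1.2293
6.25	1.24318
6.35	1.26292
6.45	1.23431
6.55	1.23046
6.65	1.22402
6.75	1.18186
6.85	1.15284
6.95	1.09664
7.05	1.1038
7.15	1.05057
7.25	1.02494
7.35	1.00996
7.45	1.00282
7.55	0.98347
7.65	0.96033
7.75	0.95725
7.85	0.9812
7.95	0.97739
8.05	0.98244
8.15	0.99714
8.25	0.99352
8.35	1.01382
8.45	1.02474
8.55	1.02788
8.65	1.0312
8.75	1.02021
8.85	1.01688
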