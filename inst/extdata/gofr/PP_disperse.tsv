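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
2.65	0
2.75	0
2.85	0
2.95	0
3.05	0.05245
3.15	0.24587
3.25	0.83151
3.35	1.65218
3.45	2.50068
3.55	2.63281
3.65	3.22304
3.75	3.99031
3.85	3.45653
3.95	2.59571
4.05	2.49887
4.15	2.40823
4.25	2.05311
4.35	1.98559
4.45	2.09449
4.55	1.90915
4.65	1.76023
4.75	1.60038
4.85	1.74252
4.95	1.47368
5.05	1.5881
5.15	1.26946
5.25	1.20385
5.35	0.98879
5.45	1.14998
5.55	1.26732
5.65	0.99358
5.75	1.34305
5.85	1.15494
5.95	1.14401
6.05	0.99985
6.15	1.16113
6.25	1.29915
6.35	1.16175
6.45	1.18465
6.55	1.04639
6.65	1.02619
6.75	1.07098
6.85	0.91514
6.95	1.03043
7.05	1.17813
7.15	1.16449
7.25	0.9562
7.35	1.02972
7.45	1.00226
7.55	1.11286
7.65	1.09229
7.75	0.8693
7.85	0.91856
7.95	0.94192
8.05	0.98644
8.15	0.90361
8.25	1.06107
8.35	0.90983
8.45	1.01144
8.55	1.03464
8.65	0.90651
8.75	0.84767
8.85	0.89092
8.95	0.8955
9.05	0.73282
9.15	0.9442
9.25	0.88398
9.35	0.84284
9.45	0.92892
9.55	0.85071
9.65	0.91702
9.75	0.98043
9.85	0.95056
9.95	0.82312
10.05	0.85513
10.15	0.96626
10.25	0.86854
10.35	0.98393
10.45	0.9071
10.55	0.79792
10.65	0.90777
10.75	0.78117
10.85	0.87876
10.95	0.83022
11.05	0.85123
11.15	0.83211
11.25	0.96775
11.35	0.88259
11.45	0.9119
11.55	0.86326
11.65	0.84131
11.75	0.95429
11.85	0.94868
11.95	0.92604
12.05	0.90737
12.15	0.93216
12.25	0.88774
12.35	0.94061
12.45	1.0137
12.55	0.95734
12.65	0.91482
12.75	0.96956
12.85	0.96044
12.95	0.9253
13.05	0.91977
13.15	0.91148
13.25	0.91723
13.35	0.98568
13.45	0.89824
13.55	0.98603
13.65	0.99783
13.75	0.95497
13.85	0.98957
13.95	0.86259
14.05	0.85777
14.15	0.91637
14.25	0.91316
14.35	0.95972
14.45	0.92078
14.55	0.82288
14.65	0.85943
14.75	0.91062
14.85	0.98691
14.95	0.89297
15.05	0.90484
15.15	0.91632
15.25	0.93162
15.35	0.88431
15.45	0.88108
15.55	0.92427
15.65	0.91648
15.75	0.90292
15.85	0.90904
15.95	0.9111
16.05	0.97366
16.15	0.89241
16.25	0.91473
16.35	0.95834
16.45	0.94492
16.55	0.98164
16.65	0.90475
16.75	0.9966
16.85	0.90574
16.95	0.97662
17.05	0.99541
17.15	0.96393
17.25	0.91506
17.35	0.94183
17.45	1.01119
17.55	1.02188
17.65	0.97274
17.75	1.00363
17.85	0.94494
17.95	1.05408
18.05	0.97054
18.15	0.9895
18.25	1.00946
18.35	0.99994
18.45	1.00203
18.55	0.98558
18.65	0.96943
18.75	1.01741
18.85	0.93935
18.95	0.99605
19.05	0.991
19.15	1.00596
19.25	0.97841
19.35	0.96311
19.45	0.99838
19.55	0.96011
19.65	1.02998
19.75	1.03333
19.85	0.96846
19.95	0.98697
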