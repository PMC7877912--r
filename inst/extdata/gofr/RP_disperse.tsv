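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
2.75	0.08954
2.85	0.39597
2.95	1.90629
3.05	3.71228
3.15	4.24806
3.25	5.30489
3.35	5.53596
3.45	5.26238
3.55	4.9701
3.65	4.87941
3.75	4.10502
3.85	3.87171
3.95	2.91866
4.05	2.84856
4.15	2.59499
4.25	2.19315
4.35	2.30819
4.45	1.9577
4.55	2.06068
4.65	1.76161
4.75	1.73324
4.85	1.65531
4.95	1.63746
5.05	1.34756
5.15	1.3851
5.25	1.37583
5.35	1.42543
5.45	1.4135
5.55	1.33005
5.65	1.3046
5.75	1.28522
5.85	1.22681
5.95	1.31025
6.05	1.2488
6.15	1.22194
6.25	1.26984
6.35	1.04122
6.45	1.15975
6.55	1.0891
6.65	1.22886
6.75	1.17042
6.85	1.15454
6.95	1.09702
7.05	1.02184
7.15	1.10937
7.25	0.96947
7.35	0.99341
7.45	1.07672
7.55	1.04245
7.65	1.16291
7.75	1.02599
7.85	0.96979
7.95	0.96162
8.05	0.9222
8.15	0.97618
8.25	0.9626
8.35	1.03438
8.45	1.00056
8.55	1.02129
8.65	0.97971
8.75	0.97956
8.85	0.92297
8.95	1.01447
9.05	0.91156
9.15	0.90792
9.25	1.03877
9.35	0.9547
9.45	0.90238
9.55	0.95783
9.65	0.94899
9.75	0.96346
9.85	0.95447
9.95	0.93196
10.05	0.96714
10.15	0.92517
10.25	0.90076
10.35	0.98458
10.45	0.97513
10.55	0.97347
10.65	0.97915
10.75	0.96102
10.85	0.92182
10.95	0.94036
11.05	0.89846
11.15	0.91918
11.25	0.99788
11.35	0.94884
11.45	0.95945
11.55	0.92388
11.65	1.00912
11.75	1.00305
11.85	0.93315
11.95	0.97687
12.05	0.98288
12.15	0.86355
12.25	0.98376
12.35	0.95125
12.45	0.89125
12.55	0.92224
12.65	0.97226
12.75	0.93207
12.85	0.94633
12.95	0.90956
13.05	0.94836
13.15	0.95064
13.25	1.01252
13.35	0.93567
13.45	0.91806
13.55	1.00046
13.65	0.96314
13.75	0.9447
13.85	0.97965
13.95	0.97174
14.05	0.93909
14.15	0.95546
14.25	0.9421
14.35	0.9175
14.45	0.97944
14.55	0.97882
14.65	0.97891
14.75	0.92211
14.85	0.97422
14.95	0.94002
15.05	0.96793
15.15	0.95446
15.25	0.92742
15.35	0.91825
15.45	0.97591
15.55	0.9746
15.65	0.99121
15.75	0.96229
15.85	0.99466
15.95	0.98755
16.05	0.9628
16.15	0.98986
16.25	0.97771
16.35	0.94806
16.45	0.99662
16.55	0.95433
16.65	0.9887
16.75	0.9715
16.85	0.96716
16.95	0.94164
17.05	0.93762
17.15	1.02399
17.25	0.9581
17.35	0.96734
17.45	0.9813
17.55	0.9729
17.65	0.98038
17.75	0.9511
17.85	0.95641
17.95	0.98046
18.05	0.93481
18.15	0.97593
18.25	0.94544
18.35	0.96483
18.45	0.95937
18.55	0.95643
18.65	0.93745
18.75	0.98574
18.85	0.92528
18.95	0.97306
19.05	0.99833
19.15	0.96023
19.25	0.99322
19.35	0.95269
19.45	0.99796
19.55	0.99885
19.65	1.00362
19.75	0.98914
19.85	0.95299
19.95	0.99238
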