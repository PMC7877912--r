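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
2.75	0.17781
2.85	0.49666
2.95	1.85426
3.05	2.9634
3.15	5.96307
3.25	6.1747
3.35	6.47063
3.45	5.59257
3.55	5.70878
3.65	5.40027
3.75	5.30737
3.85	4.08264
3.95	3.31832
4.05	3.15648
4.15	3.20141
4.25	2.64305
4.35	2.23866
4.45	2.275
4.55	1.98123
4.65	1.67925
4.75	1.22187
4.85	1.31493
4.95	1.56421
5.05	1.7929
5.15	1.21691
5.25	1.53693
5.35	1.59747
5.45	1.29037
5.55	1.33161
5.65	1.07425
5.75	1.01688
5.85	1.37537
5.95	1.29155
6.05	0.9369
6.15	1.31558
6.25	1.22218
6.35	1.16731
6.45	1.03442
6.55	1.09711
6.65	1.21642
6.75	1.04782
6.85	1.06044
6.95	0.9327
7.05	1.20406
7.15	1.0654
7.25	0.84432
7.35	1.07044
7.45	1.00555
7.55	1.06166
7.65	1.14899
7.75	1.01877
7.85	0.93842
7.95	0.78729
8.05	0.94425
8.15	0.83011
8.25	0.84963
8.35	0.97407
8.45	0.80047
8.55	0.86464
8.65	1.01551
8.75	0.87826
8.85	1.03023
8.95	0.99894
9.05	0.91952
9.15	0.93166
9.25	0.97449
9.35	0.94607
9.45	0.91862
9.55	0.86262
9.65	0.95315
9.75	0.89833
9.85	0.94949
9.95	0.94408
10.05	0.92539
10.15	1.03778
10.25	1.01763
10.35	1.042
10.45	1.03447
10.55	1.0512
10.65	1.04341
10.75	0.94263
10.85	0.78253
10.95	0.99824
11.05	0.96373
11.15	0.91407
11.25	0.9032
11.35	0.91868
11.45	1.03093
11.55	0.89722
11.65	0.95124
11.75	0.94973
11.85	0.84279
11.95	1.07831
12.05	1.05585
12.15	1.06587
12.25	0.91411
12.35	0.86851
12.45	1.0802
12.55	0.99901
12.65	1.00429
12.75	0.99274
12.85	0.95291
12.95	1.00641
13.05	0.88049
13.15	0.94493
13.25	0.91923
13.35	0.98851
13.45	1.0036
13.55	0.98884
13.65	1.02133
13.75	0.91761
13.85	1.02009
13.95	0.89494
14.05	0.95719
14.15	0.93363
14.25	0.88084
14.35	1.02208
14.45	0.8695
14.55	0.94653
14.65	0.98691
14.75	0.87467
14.85	0.90257
14.95	0.93567
15.05	0.91437
15.15	0.97851
15.25	0.94259
15.35	0.9332
15.45	0.93806
15.55	0.97331
15.65	1.01033
15.75	1.00838
15.85	1.06529
15.95	0.93039
16.05	0.95016
16.15	0.90233
16.25	1.08734
16.35	0.97849
16.45	1.00639
16.55	0.95499
16.65	1.03815
16.75	0.97306
16.85	1.09417
16.95	1.03449
17.05	0.98538
17.15	1.0105
17.25	1.00108
17.35	0.97617
17.45	0.97606
17.55	0.99553
17.65	0.97349
17.75	1.00524
17.85	0.96657
17.95	0.98922
18.05	0.86065
18.15	0.97979
18.25	0.93678
18.35	1.02844
18.45	0.99362
18.55	1.03765
18.65	1.06328
18.75	1.01754
18.85	1.01435
18.95	0.96996
19.05	0.90237
19.15	1.01765
19.25	1.01074
19.35	1.05599
19.45	0.97939
19.55	0.98523
19.65	0.96304
19.75	0.974
19.85	1.03418
19.95	0.98498
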