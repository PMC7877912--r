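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
2.55	0.14847
2.65	0.13748
2.75	0.76596
2.85	1.54517
2.95	1.33126
3.05	2.17946
3.15	2.43249
3.25	2.28511
3.35	1.89264
3.45	1.54118
3.55	1.53219
3.65	2.02915
3.75	1.57909
3.85	1.6284
3.95	1.42324
4.05	1.41269
4.15	1.23331
4.25	1.49668
4.35	1.02047
4.45	1.07264
4.55	1.07264
4.65	1.25027
4.75	0.94143
4.85	0.73883
4.95	0.66987
5.05	0.98434
5.15	1.1285
5.25	1.05089
5.35	1.58543
5.45	1.1052
5.55	1.12843
5.65	1.05859
5.75	0.81767
5.85	0.95923
5.95	1.03635
6.05	0.89686
6.15	1.04663
6.25	1.18642
6.35	1.10146
6.45	1.27645
6.55	0.87769
6.65	1.00433
6.75	1.16551
6.85	0.90538
6.95	1.15936
7.05	1.01015
7.15	1.05764
7.25	1.19398
7.35	1.16172
7.45	1.26991
7.55	0.96548
7.65	0.82491
7.75	1.15742
7.85	1.09678
7.95	1.05409
8.05	1.01316
8.15	1.14835
8.25	1.00719
8.35	0.78934
8.45	1.0953
8.55	1.13587
8.65	0.96782
8.75	1.10976
8.85	0.92457
8.95	1.13304
9.05	1.06098
9.15	1.01486
9.25	0.92533
9.35	0.94982
9.45	1.04875
9.55	1.20688
9.65	0.86057
9.75	0.99536
9.85	1.01506
9.95	0.92649
10.05	1.12801
10.15	0.97469
10.25	0.97414
10.35	1.0816
10.45	0.97258
10.55	0.97158
10.65	0.99598
10.75	1.01096
10.85	1.12364
10.95	1.11126
11.05	1.05961
11.15	1.08729
11.25	0.95361
11.35	1.03431
11.45	1.08261
11.55	0.96262
11.65	1.1667
11.75	1.10496
11.85	1.05889
11.95	1.10209
12.05	1.02403
12.15	1.13805
12.25	1.11311
12.35	1.12681
12.45	0.94683
12.55	1.01149
12.65	1.0378
12.75	1.05128
12.85	1.12269
12.95	1.0536
13.05	1.03752
13.15	1.14464
13.25	1.05593
13.35	1.15394
13.45	1.10482
13.55	1.12013
13.65	1.10896
13.75	1.09289
13.85	0.98656
13.95	1.05185
14.05	1.10541
14.15	1.08502
14.25	1.18396
14.35	0.96589
14.45	1.0728
14.55	1.06723
14.65	1.0752
14.75	1.0296
14.85	1.06833
14.95	1.08
15.05	1.07422
15.15	1.11898
15.25	1.2206
15.35	1.19246
15.45	1.05168
15.55	1.12205
15.65	0.96978
15.75	1.05092
15.85	1.0377
15.95	0.98678
16.05	0.97077
16.15	1.04023
16.25	1.02746
16.35	1.05105
16.45	0.99906
16.55	0.913
16.65	1.08318
16.75	1.01522
16.85	1.02021
16.95	0.94435
17.05	1.03627
17.15	0.95857
17.25	0.99616
17.35	0.93339
17.45	1.02419
17.55	1.08778
17.65	0.94222
17.75	1.05115
17.85	0.99092
17.95	0.9889
18.05	1.02835
18.15	1.11084
18.25	1.01174
18.35	1.12977
18.45	0.96439
18.55	0.96525
18.65	1.01877
18.75	0.97223
18.85	0.95379
18.95	0.98139
19.05	0.9924
19.15	0.96363
19.25	1.01097
19.35	0.92576
19.45	1.03367
19.55	1.05091
19.65	0.95272
19.75	0.96785
19.85	0.93607
19.95	0.98008
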