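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
2.55	0.03796
2.65	0.42184
2.75	0.65287
2.85	1.45886
2.95	1.67368
3.05	1.59228
3.15	1.69183
3.25	1.63607
3.35	1.49587
3.45	1.32745
3.55	1.56715
3.65	1.48246
3.75	1.08845
3.85	0.88275
3.95	1.21837
4.05	1.26431
4.15	1.10377
4.25	0.99777
4.35	1.14813
4.45	1.03477
4.55	0.98979
4.65	1.05044
4.75	0.95197
4.85	0.97609
4.95	1.05796
5.05	1.10361
5.15	0.91223
5.25	0.96738
5.35	0.89706
5.45	1.02236
5.55	0.94578
5.65	1.04408
5.75	1.11262
5.85	0.80077
5.95	1.00421
6.05	0.96454
6.15	1.05092
6.25	0.97332
6.35	0.91842
6.45	0.99698
6.55	0.99555
6.65	0.93233
6.75	1.0187
6.85	0.92078
6.95	0.9967
7.05	1.06797
7.15	0.90309
7.25	0.97698
7.35	0.98714
7.45	0.93413
7.55	1.02216
7.65	1.07155
7.75	0.99064
7.85	1.06572
7.95	0.96095
8.05	0.97913
8.15	0.89578
8.25	0.92498
8.35	0.99857
8.45	1.07189
8.55	0.99968
8.65	0.9866
8.75	0.88356
8.85	0.92044
8.95	1.00479
9.05	1.00983
9.15	0.99378
9.25	0.92047
9.35	1.03927
9.45	0.95656
9.55	0.9231
9.65	1.03398
9.75	0.9064
9.85	0.96697
9.95	0.8803
10.05	0.86531
10.15	0.9442
10.25	0.91647
10.35	0.96569
10.45	0.93825
10.55	0.90724
10.65	0.87504
10.75	0.98062
10.85	0.91229
10.95	0.91835
11.05	0.85126
11.15	0.9711
11.25	0.98122
11.35	0.91226
11.45	0.85308
11.55	0.89945
11.65	0.94592
11.75	0.96387
11.85	0.92129
11.95	0.93187
12.05	0.96748
12.15	0.85796
12.25	0.88185
12.35	0.89677
12.45	0.97639
12.55	0.92171
12.65	0.92416
12.75	0.93402
12.85	0.88216
12.95	1.00256
13.05	0.97131
13.15	0.97373
13.25	0.96049
13.35	0.942
13.45	0.9376
13.55	0.90095
13.65	0.97658
13.75	0.95067
13.85	0.94858
13.95	0.90458
14.05	0.99681
14.15	0.92728
14.25	0.93984
14.35	0.97714
14.45	0.9684
14.55	0.88865
14.65	0.93178
14.75	0.9033
14.85	0.8923
14.95	0.94005
15.05	0.91234
15.15	0.95305
15.25	0.91829
15.35	0.92837
15.45	0.93501
15.55	0.94753
15.65	0.97376
15.75	0.92063
15.85	0.95819
15.95	0.94718
16.05	0.98621
16.15	0.94753
16.25	0.95086
16.35	0.96051
16.45	0.96712
16.55	1.01946
16.65	0.93066
16.75	0.95742
16.85	1.03653
16.95	0.97106
17.05	1.00641
17.15	1.01821
17.25	1.03963
17.35	0.93172
17.45	0.97134
17.55	1.0092
17.65	0.9019
17.75	0.95446
17.85	0.97401
17.95	1.04671
18.05	1.01241
18.15	1.01702
18.25	1.00072
18.35	0.98031
18.45	0.94651
18.55	1.03462
18.65	1.01575
18.75	0.98528
18.85	1.05198
18.95	1.02922
19.05	1.0232
19.15	1.01322
19.25	1.02138
19.35	1.01348
19.45	1.02593
19.55	0.978
19.65	1.00579
19.75	0.98867
19.85	0.99879
19.95	1.01609
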