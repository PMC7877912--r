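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
2.95	0.01028
3.05	0.0878
3.15	0.41606
3.25	1.02534
3.35	1.69779
3.45	2.38194
3.55	2.57102
3.65	2.60844
3.75	2.48153
3.85	2.30071
3.95	2.02722
4.05	1.74349
4.15	1.60397
4.25	1.4024
4.35	1.21745
4.45	1.07521
4.55	1.06035
4.65	0.9754
4.75	0.93278
4.85	0.889
4.95	0.88404
5.05	0.87789
5.15	0.88252
5.25	0.93609
5.35	0.96475
5.45	1.00125
5.55	1.03741
5.65	1.12439
5.75	1.14315
5.85	1.23943
5.95	1.25975
6.05	1.27439
6.15	1.30724
6.25	1.34824
6.35	1.35855
6.45	1.31945
6.55	1.33058
6.65	1.28682
6.75	1.22908
6.85	1.21516
6.95	1.18878
7.05	1.16543
7.15	1.1081
7.25	1.08605
7.35	1.05691
7.45	1.06037
7.55	1.01166
7.65	0.98386
7.75	0.99496
7.85	0.95997
7.95	0.97509
8.05	0.97329
8.15	0.96387
8.25	0.97566
8.35	0.95051
8.45	1.01574
8.55	1.01355
8.65	0.99533
8.75	1.0072
8.85	1.043
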