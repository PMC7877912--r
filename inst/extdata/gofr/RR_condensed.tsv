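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
2.45	0.01864
2.55	0.2008
2.65	0.78755
2.75	1.44168
2.85	2.10818
2.95	2.33207
3.05	2.31501
3.15	2.13372
3.25	1.85433
3.35	1.58156
3.45	1.52412
3.55	1.32624
3.65	1.14535
3.75	1.07646
3.85	0.95772
3.95	0.93794
4.05	0.89447
4.15	0.82589
4.25	0.84067
4.35	0.83746
4.45	0.78706
4.55	0.87584
4.65	0.84418
4.75	0.87598
4.85	0.92231
4.95	0.98706
5.05	1.04382
5.15	1.06417
5.25	1.13535
5.35	1.15815
5.45	1.21465
5.55	1.23123
5.65	1.26429
5.75	1.29461
5.85	1.31941
5.95	1.36739
6.05	1.3404
6.15	1.31911
6.25	1.31759
6.35	1.29007
6.45	1.27325
6.55	1.24401
6.65	1.20013
6.75	1.14846
6.85	1.12889
6.95	1.08158
7.05	1.0209
7.15	1.03286
7.25	0.99676
7.35	0.9952
7.45	0.95757
7.55	0.96576
7.65	0.97861
7.75	0.97137
7.85	0.98871
7.95	0.97993
8.05	0.98309
8.15	0.99534
8.25	1.02645
8.35	1.01873
8.45	1.04284
8.55	1.02471
8.65	1.03668
8.75	1.06478
8.85	1.07146
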