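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
3.05	0
3.15	0.20078
3.25	1.13167
3.35	1.42017
3.45	3.18021
3.55	3.794
3.65	3.88805
3.75	3.82513
3.85	4.16665
3.95	4.59681
4.05	4.00823
4.15	2.77629
4.25	3.19868
4.35	2.63217
4.45	2.81703
4.55	2.98327
4.65	2.21136
4.75	1.85433
4.85	1.86335
4.95	1.78883
5.05	1.79681
5.15	1.95306
5.25	1.59024
5.35	1.67056
5.45	1.47567
5.55	2.13446
5.65	1.56028
5.75	1.68726
5.85	1.80472
5.95	1.29436
6.05	1.36079
6.15	1.63295
6.25	1.3771
6.35	0.83997
6.45	1.19724
6.55	1.39316
6.65	1.12631
6.75	0.96201
6.85	1.23135
6.95	1.23741
7.05	0.68145
7.15	1.44196
7.25	1.06132
7.35	1.03264
7.45	1.07689
7.55	1.29322
7.65	1.19154
7.75	0.89562
7.85	1.39025
7.95	1.19788
8.05	0.92235
8.15	1.25979
8.25	0.93672
8.35	1.25732
8.45	0.94871
8.55	1.28095
8.65	1.35801
8.75	1.06693
8.85	1.09383
8.95	0.9949
9.05	0.99736
9.15	1.30884
9.25	1.1177
9.35	0.88881
9.45	1.16013
9.55	1.31072
9.65	0.89859
9.75	0.94313
9.85	1.14996
9.95	0.8251
10.05	1.10465
10.15	1.45043
10.25	1.08092
10.35	1.06014
10.45	0.6933
10.55	1.34253
10.65	1.00125
10.75	1.13788
10.85	1.18469
10.95	1.21301
11.05	0.83217
11.15	1.04167
11.25	1.0075
11.35	1.26821
11.45	1.0182
11.55	1.5383
11.65	0.99822
11.75	1.18333
11.85	1.16344
11.95	1.03244
12.05	1.26236
12.15	1.03922
12.25	1.2082
12.35	1.1234
12.45	0.97689
12.55	1.15113
12.65	1.14545
12.75	0.98048
12.85	1.03767
12.95	1.22368
13.05	0.95932
13.15	0.99087
13.25	1.20294
13.35	1.2856
13.45	0.9802
13.55	1.21537
13.65	1.10139
13.75	1.01166
13.85	1.0802
13.95	1.12619
14.05	1.16069
14.15	0.98513
14.25	1.06946
14.35	1.04493
14.45	1.02098
14.55	1.14816
14.65	0.90046
14.75	0.93408
14.85	1.00286
14.95	1.19452
15.05	1.1611
15.15	1.08506
15.25	1.15655
15.35	0.93859
15.45	1.24365
15.55	0.8734
15.65	1.2202
15.75	1.10035
15.85	1.16581
15.95	1.26088
16.05	1.09053
16.15	0.94721
16.25	1.08649
16.35	1.01362
16.45	1.02342
16.55	0.93835
16.65	1.06366
16.75	1.02259
16.85	1.0947
16.95	1.20665
17.05	1.1377
17.15	1.10415
17.25	1.2253
17.35	1.14503
17.45	0.988
17.55	0.99618
17.65	1.05527
17.75	1.11298
17.85	1.06302
17.95	1.15015
18.05	1.0396
18.15	1.19147
18.25	1.08872
18.35	1.09464
18.45	1.04768
18.55	1.19854
18.65	1.08262
18.75	1.1391
18.85	1.05416
18.95	1.18731
19.05	1.02116
19.15	1.14091
19.25	1.13984
19.35	1.07488
19.45	1.12705
19.55	1.04779
19.65	0.94427
19.75	1.13394
19.85	0.9759
19.95	1.03122
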