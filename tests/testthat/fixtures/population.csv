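age,sex,count
0,F,3342795
1,F,3215851
2,F,3276075
3,F,3293786
4,F,3278750
5,F,3245439
6,F,3352140
7,F,3246151
8,F,3386259
9,F,3248184
10,F,3338226
11,F,3404390
12,F,3163076
13,F,3234046
14,F,3243423
15,F,3293656
16,F,3233533
17,F,3083636
18,F,3096907
19,F,3338716
20,F,3231731
21,F,3137686
22,F,3240180
23,F,3331122
24,F,3376569
25,F,3222890
26,F,3233818
27,F,3137588
28,F,3279905
29,F,3208140
30,F,3278744
31,F,3294606
32,F,3315823
33,F,3207881
34,F,3279335
35,F,3135899
36,F,3193884
37,F,3188432
38,F,3088932
39,F,3242444
40,F,3251586
41,F,3212761
42,F,3282948
43,F,3184047
44,F,3140225
45,F,3251553
46,F,3167317
47,F,3308265
48,F,3180708
49,F,3243856
50,F,3214562
51,F,3135591
52,F,3276699
53,F,3204426
54,F,3155918
55,F,3152522
56,F,3160513
57,F,3103753
58,F,2897061
59,F,3067768
60,F,2999397
61,F,2988920
62,F,2952189
63,F,2910924
64,F,2864731
65,F,2813234
66,F,2756082
67,F,2692971
68,F,2623666
69,F,2548022
70,F,2466005
71,F,2377717
72,F,2283412
73,F,2183511
74,F,2078605
75,F,1969452
76,F,1856964
77,F,1742176
78,F,1626215
79,F,1510254
80,F,1395466
81,F,1282978
82,F,1173826
83,F,1068920
84,F,969018
85,F,874713
86,F,786425
87,F,704409
88,F,628764
89,F,559460
90,F,496349
91,F,439197
92,F,387699
93,F,341507
94,F,300242
95,F,263511
96,F,230923
97,F,202092
98,F,176650
99,F,154249
100,F,134565
0,M,3321057
1,M,3187770
2,M,3374857
3,M,3209275
4,M,3259218
5,M,3224984
6,M,3244371
7,M,3264567
8,M,3260043
9,M,3250629
10,M,3259271
11,M,3220782
12,M,3219538
13,M,3145862
14,M,3227310
15,M,3218857
16,M,3432532
17,M,3164503
18,M,3260754
19,M,3156020
20,M,3157378
21,M,3259605
22,M,3187173
23,M,3251054
24,M,3223253
25,M,3211103
26,M,3121505
27,M,3171557
28,M,3261551
29,M,3286567
30,M,3217143
31,M,3248493
32,M,3321650
33,M,3342056
34,M,3175926
35,M,3237851
36,M,3323296
37,M,3212832
38,M,3238338
39,M,3234527
40,M,3181234
41,M,3207393
42,M,3231640
43,M,3204032
44,M,3300017
45,M,3192667
46,M,3191367
47,M,3259191
48,M,3141201
49,M,3198993
50,M,3096343
51,M,3260361
52,M,3157717
53,M,3134025
54,M,3073199
55,M,3134647
56,M,3068360
57,M,3065300
58,M,3156022
59,M,3039649
60,M,2957429
61,M,2988920
62,M,2952189
63,M,2910924
64,M,2864731
65,M,2813234
66,M,2756082
67,M,2692971
68,M,2623666
69,M,2548022
70,M,2466005
71,M,2377717
72,M,2283412
73,M,2183511
74,M,2078605
75,M,1969452
76,M,1856964
77,M,1742176
78,M,1626215
79,M,1510254
80,M,1395466
81,M,1282978
82,M,1173826
83,M,1068920
84,M,969018
85,M,874713
86,M,786425
87,M,704409
88,M,628764
89,M,559460
90,M,496349
91,M,439197
92,M,387699
93,M,341507
94,M,300242
95,M,263511
96,M,230923
97,M,202092
98,M,176650
99,M,154249
100,M,134565
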