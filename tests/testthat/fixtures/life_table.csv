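age,sex,q_all_cause
0,F,4.9998750020833077e-5
1,F,5.470721769084718e-5
2,F,5.985907653007192e-5
3,F,6.54960775749153e-5
4,F,7.166390274785009e-5
5,F,7.841253485098095e-5
6,F,8.579666236507456e-5
7,F,9.387612232425823e-5
8,F,1.0271638484306721e-4
9,F,1.123890832075646e-4
10,F,1.2297259380850183e-4
11,F,1.3455267059479966e-4
12,F,1.4722313916313608e-4
13,F,1.610866560775324e-4
14,F,1.7625553953523363e-4
15,F,1.9285267806591532e-4
16,F,2.1101252457470023e-4
17,F,2.3088218372038538e-4
18,F,2.5262260136384363e-4
19,F,2.764098656333705e-4
20,F,3.0243663003987753e-4
21,F,3.3091367004187063e-4
22,F,3.6207158551520874e-4
23,F,3.9616266273341186e-4
24,F,4.334629107190637e-4
25,F,4.7427428819458154e-4
26,F,5.189271388509082e-4
27,F,5.677828542758266e-4
28,F,6.212367856506633e-4
29,F,6.797214272469147e-4
30,F,7.437098968453738e-4
31,F,8.137197404729787e-4
32,F,8.903170913209453e-4
33,F,9.741212153866553e-4
34,F,0.001065809479286701
35,F,0.0011661227788357102
36,F,0.0012758714703916694
37,F,0.0013959418506505248
38,F,0.0015273032345481333
39,F,0.0016710156852132617
40,F,0.0018282384545280602
41,F,0.002000239197808211
42,F,0.0021884040314282052
43,F,0.0023942485079004932
44,F,0.002619429588980025
45,F,0.0028657587038135937
46,F,0.0031352159859867577
47,F,0.0034299657905332848
48,F,0.00375237359954797
49,F,0.004105024432956681
50,F,0.004490742889207424
51,F,0.004912614949095063
52,F,0.005374011684541141
53,F,0.005878615022812931
54,F,0.006430445725244575
55,F,0.007033893747840288
56,F,0.007693751158969869
57,F,0.008415247796427544
58,F,0.009204089852063748
59,F,0.010066501576581345
60,F,0.011009270299378367
61,F,0.012039794957866834
62,F,0.01316613832671052
63,F,0.014397083128948248
64,F,0.015742192196854146
65,F,0.017211872829259834
66,F,0.018817445462287547
67,F,0.020571216730079722
68,F,0.022486556938869983
69,F,0.02457798190893709
70,F,0.026861239051480044
71,F,0.02935339743760614
72,F,0.03207294148023329
73,F,0.035039867681957416
74,F,0.03827578369735427
75,F,0.04180400871061143
76,F,0.045649673831959274
77,F,0.04983982086154811
78,F,0.05440349734905151
79,F,0.059371845382731346
80,F,0.06477818096409313
81,F,0.07065806015479571
82,F,0.07704932741295392
83,F,0.08399214065949087
84,F,0.09152896662713764
85,F,0.09970453894401178
86,F,0.10856577019469177
87,F,0.11816160789609882
88,F,0.12854282294532787
89,F,0.13976171767756126
90,F,0.15187173926792116
91,F,0.16492698289789873
92,F,0.178981567989498
93,F,0.19408887002765512
94,F,0.21030059022401856
95,F,0.22766564575016923
96,F,0.2462288647655366
97,F,0.26602947331950655
98,F,0.2870993658073743
99,F,0.3094611574410068
100,F,1
0,M,7.499718757031119e-5
1,M,8.2059704196162e-5
2,M,8.978727111581135e-5
3,M,9.824250769374581e-5
4,M,1.0749392820566279e-4
5,M,1.1761649654922979e-4
6,M,1.28692233107911e-4
7,M,1.408108786623005e-4
8,M,1.5407062070097217e-4
9,M,1.6857888798285777e-4
10,M,1.844532197494604e-4
11,M,2.0182221658200533e-4
12,M,2.2082658055049058e-4
13,M,2.4162025301349403e-4
14,M,2.6437165920489917e-4
15,M,2.892650695922637e-4
16,M,3.1650208891770585e-4
17,M,3.463032848427554e-4
18,M,3.7890996922103034e-4
19,M,4.1458614622483784e-4
20,M,4.536206428624709e-4
21,M,4.963294388513719e-4
22,M,5.430582143683914e-4
23,M,5.941851358928057e-4
24,M,6.501239022019429e-4
25,M,7.113270745854322e-4
26,M,7.782897175251558e-4
27,M,8.515533784576783e-4
28,M,9.317104378087416e-4
29,M,0.0010194088632805125
30,M,0.0011153574053975619
31,M,0.00122033127459341
32,M,0.0013351783436628501
33,M,0.0014608259232333032
34,M,0.0015982881620383584
35,M,0.0017486741282255103
36,M,0.0019131966327141962
37,M,0.0020931818607548788
38,M,0.0022900798833387376
39,M,0.002505476125981533
40,M,0.0027411038786621317
41,M,0.002998857937339173
42,M,0.003280809474495348
43,M,0.0035892222435572867
44,M,0.003926570229789319
45,M,0.004295556868328391
46,M,0.004699135958366608
47,M,0.00514053441102887
48,M,0.005623276977144231
49,M,0.006151213109749437
50,M,0.006728546124634652
51,M,0.007359864830344006
52,M,0.00805017780652465
53,M,0.008804950516060655
54,M,0.009630145441640578
55,M,0.010532265440806566
56,M,0.011518400514527316
57,M,0.012596278182208173
58,M,0.013774317649927363
59,M,0.015061687947519711
60,M,0.016468370192659343
61,M,0.01800522411481938
62,M,0.01968405893712537
63,M,0.021517708667560805
64,M,0.023520111790242663
65,M,0.025706395269658205
66,M,0.028092962682452344
67,M,0.030697586168662305
68,M,0.03353950174270528
69,M,0.03663950731879527
70,M,0.04002006257997993
71,M,0.04370538954813051
72,M,0.047721572386781375
73,M,0.05209665458183444
74,M,0.056860731188406524
75,M,0.06204603329670675
76,M,0.06768700124689768
77,M,0.07382034240384334
78,M,0.080485068479837385
79,M,0.0877225064609446
80,M,0.09557627614748687
81,M,0.10409222616286003
82,M,0.11331831902501674
83,M,0.12330445452815662
84,M,0.13410221927689284
85,M,0.14576454879560258
86,M,0.15834528726621194
87,M,0.17189862871822056
88,M,0.1864784225266481
89,M,0.20213732552587937
90,M,0.21892578312337896
91,M,0.23689082275022572
92,M,0.25607464512280814
93,M,0.27651300247446114
94,M,0.2982333585610281
95,M,0.321252833303067
96,M,0.34557594586815354
97,M,0.37119218426483597
98,M,0.39807344747869405
99,M,0.4261714280286649
100,M,1
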