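age,sex,p_cad_first,case_fatality
0,F,1.1999280028799137e-4,0.02
1,F,1.2998599920883175e-4,0.022
2,F,1.4081138966452706e-4,0.024
3,F,1.5253826289452697e-4,0.026000000000000002
4,F,1.652416778101214e-4,0.028
5,F,1.7900294077841819e-4,0.03
6,F,1.9391012526404002e-4,0.032
7,F,2.100586346304674e-4,0.034
8,F,2.2755181167489436e-4,0.036000000000000004
9,F,2.465015987645179e-4,0.038000000000000006
10,F,2.6702925276010333e-4,0.04
11,F,2.8926611925633624e-4,0.041999999999999996
12,F,3.13354471039904e-4,0.044
13,F,3.3944841606760805e-4,0.046
14,F,3.6771488070041537e-4,0.048
15,F,3.983346743976868e-4,0.05
16,F,4.315036425815329e-4,0.052000000000000005
17,F,4.6743391492716664e-4,0.054000000000000006
18,F,5.063552569242764e-4,0.05600000000000001
19,F,5.485165331900331e-4,0.057999999999999996
20,F,5.941872916997955e-4,0.06
21,F,6.436594788405106e-4,0.062
22,F,6.972492959880349e-4,0.064
23,F,7.552992091671884e-4,0.066
24,F,8.18180124276543e-4,0.068
25,F,8.86293741353181e-4,0.07
26,F,9.600751024206322e-4,0.07200000000000001
27,F,0.0010399953486107101,0.074
28,F,0.0011265647034820624,0.076
29,F,0.0012203357007800541,0.078
30,F,0.0013219066762993835,0.08
31,F,0.001431925545027871,0.082
32,F,0.0015510938863725367,0.084
33,F,0.001680171362002506,0.08600000000000001
34,F,0.0018199804926926453,0.08800000000000001
35,F,0.001971411822521804,0.09000000000000001
36,F,0.0021354295008744824,0.09200000000000001
37,F,0.002313077314918423,0.094
38,F,0.002505485207585859,0.096
39,F,0.002713876318574868,0.098
40,F,0.002939574588509817,0.1
41,F,0.0031840129691549485,0.10200000000000001
42,F,0.0034487422854592403,0.10400000000000001
43,F,0.0037354407982174774,0.10600000000000001
44,F,0.004045924519252292,0.108
45,F,0.0043821583342412455,0.11
46,F,0.004746267991612839,0.112
47,F,0.005140553019291098,0.114
48,F,0.005567500634448182,0.116
49,F,0.006029800714787454,0.11800000000000001
50,F,0.006530361903175036,0.12000000000000001
51,F,0.007072328920602735,0.12200000000000001
52,F,0.007659101165421675,0.12400000000000001
53,F,0.008294352679439536,0.126
54,F,0.008982053563709845,0.128
55,F,0.009726492928521069,0.13
56,F,0.01053230346305023,0.132
57,F,0.011404487710182147,0.134
58,F,0.01234844613087583,0.136
59,F,0.013370007039904956,0.138
60,F,0.014475458490480587,0.13999999999999999
61,F,0.015671582178795815,0.142
62,F,0.016965689430459795,0.144
63,F,0.018365659318586417,0.146
64,F,0.019879978947355915,0.148
65,F,0.02151778591446656,0.15
66,F,0.023288912940218134,0.152
67,F,0.02520393461907892,0.154
68,F,0.027274216210406543,0.156
69,F,0.029511964337296415,0.158
70,F,0.03193027940493319,0.16
71,F,0.0345432094807608,0.162
72,F,0.03736580529652215,0.164
73,F,0.04041417593481538,0.16599999999999998
74,F,0.04370554464814522,0.16799999999999998
75,F,0.04725830412419847,0.16999999999999998
76,F,0.05109207035476094,0.172
77,F,0.05522773408468631,0.174
78,F,0.0596875086089058,0.176
79,F,0.06449497244687782,0.178
80,F,0.0696751051524477,0.18
81,F,0.07525431421036023,0.182
82,F,0.08126045062658713,0.184
83,F,0.08772281043679452,0.186
84,F,0.09467211893525276,0.188
85,F,0.10214049396623223,0.19
86,F,0.11016138412427723,0.192
87,F,0.11876947718408283,0.194
88,F,0.1280005735336733,0.19599999999999998
89,F,0.13789141882908865,0.19799999999999998
90,F,0.14847948954299933,0.19999999999999998
91,F,0.15980272456831462,0.20199999999999999
92,F,0.17189919559357394,0.204
93,F,0.18480670863183046,0.206
94,F,0.19856232891198303,0.208
95,F,0.21320182139682334,0.21
96,F,0.22875899955511814,0.212
97,F,0.24526497578049183,0.214
98,F,0.26274730812758773,0.216
99,F,0.2812290399503766,0.218
100,F,0.30072763171503736,0.22
0,M,2.3997120230386177e-4,0.02
1,M,2.599551020576732e-4,0.022
2,M,2.816029514815949e-4,0.024
3,M,3.0505325786740707e-4,0.026000000000000002
4,M,3.304560508081573e-4,0.028
5,M,3.5797383950402905e-4,0.03
6,M,3.877826493914001e-4,0.032
7,M,4.20073144630952e-4,0.034
8,M,4.550518435227922e-4,0.036000000000000004
9,M,4.929424344908423e-4,0.038000000000000006
10,M,5.33987200898377e-4,0.04
11,M,5.78448563624923e-4,0.041999999999999996
12,M,6.266107510552872e-4,0.044
13,M,6.787816069080452e-4,0.046
14,M,7.352945471673422e-4,0.048
15,M,7.965106782825462e-4,0.05
16,M,8.628210897695047e-4,0.052000000000000005
17,M,9.346493353895091e-4,0.054000000000000006
18,M,0.001012454118202338,0.05600000000000001
19,M,0.0010967321959928834,0.057999999999999996
20,M,0.0011880215248619734,0.06
21,M,0.0012869046601563202,0.062
22,M,0.001394012435395314,0.064
23,M,0.0015100279414390083,0.066
24,M,0.0016356908298373247,0.068
25,M,0.0017718019661104004,0.07
26,M,0.0019192284606389764,0.07200000000000001
27,M,0.002078909106896288,0.074
28,M,0.002251860258932993,0.076
29,M,0.00243918218233751,0.078
30,M,0.002642065915337922,0.08
31,M,0.002861800679289239,0.082
32,M,0.003099781880500731,0.084
33,M,0.0033575197481993183,0.08600000000000001
34,M,0.003636648656391509,0.08800000000000001
35,M,0.00393893718046963,0.09000000000000001
36,M,0.00426629894259576,0.09200000000000001
37,M,0.004620804303172056,0.094
38,M,0.005004692959046287,0.096
39,M,0.005420387512477215,0.098
40,M,0.005870508078258222,0.1
41,M,0.00635788799972215,0.10200000000000001
42,M,0.006885590747566966,0.10400000000000001
43,M,0.007456928078477967,0.10600000000000001
44,M,0.008075479533289097,0.108
45,M,0.008745113356816131,0.11
46,M,0.009470008923377468,0.112
47,M,0.010254680753238054,0.114
48,M,0.011104004205581783,0.116
49,M,0.012023242932914856,0.11800000000000001
50,M,0.013018078179763632,0.12000000000000001
51,M,0.014094640004844276,0.12200000000000001
52,M,0.015259540500181187,0.12400000000000001
53,M,0.016519909072508145,0.126
54,M,0.017883429841198336,0.128
55,M,0.019358381192353568,0.13
56,M,0.02095367750986268,0.132
57,M,0.0226789130804326,0.134
58,M,0.02454440813990452,0.136
59,M,0.026561256991562806,0.138
60,M,0.028741378082451547,0.13999999999999999
61,M,0.03109756586960488,0.142
62,M,0.03364354424306877,0.144
63,M,0.03639402119496646,0.146
64,M,0.03936474433176452,0.148
65,M,0.04257255671827231,0.15
66,M,0.04603545241449921,0.152
67,M,0.04977263091787503,0.154
68,M,0.05380454955092108,0.156
69,M,0.05815297263554697,0.158
70,M,0.06284101606698927,0.16
71,M,0.06789318564028987,0.162
72,M,0.07333540718758669,0.164
73,M,0.07919504625314056,0.16599999999999998
74,M,0.08550091466329943,0.16799999999999998
75,M,0.09228326093970171,0.16999999999999998
76,M,0.09957374105638604,0.172
77,M,0.10740536555724378,0.174
78,M,0.1158124185338734,0.176
79,M,0.12483034342283213,0.178
80,M,0.13449559002689074,0.18
81,M,0.14484541661344885,0.182
82,M,0.15591764041713824,0.184
83,M,0.16775032940265927,0.186
84,M,0.18038142776681487,0.188
85,M,0.19384830742479855,0.19
86,M,0.2081872376963779,0.192
87,M,0.22343276565758527,0.194
88,M,0.2396170002423973,0.19599999999999998
89,M,0.25676879427147814,0.19799999999999998
90,M,0.274912820271049,0.19999999999999998
91,M,0.2940685383571726,0.20199999999999999
92,M,0.3142490577414301,0.204
93,M,0.3354598977083306,0.206
94,M,0.3576976593610155,0.208
95,M,0.3809486261467237,0.21
96,M,0.40518731923277773,0.212
97,M,0.43037504321637843,0.214
98,M,0.4564584683268819,0.216
99,M,0.4833683069893427,0.218
100,M,0.5110181549531396,0.22
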