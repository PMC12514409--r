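age,qx
0,0.0005298595748095547
1,0.00053268330235745065
2,0.00053577294328466252
3,0.00053915353799049992
4,0.00054285248468088909
5,0.00054689976134203455
6,0.00055132816860659073
7,0.00055617359547299738
8,0.00056147531003003515
9,0.00056727627753661025
10,0.00057362350842715681
11,0.00058056843905707201
12,0.00058816734826350192
13,0.00059648181310667514
14,0.00060557920747184024
15,0.00061553324755758698
16,0.00062642458865080908
17,0.00063834147800245766
18,0.00065138046906798586
19,0.00066564720286721446
20,0.00068125726275636289
21,0.00069833710949207539
22,0.00071702510410853737
23,0.00073747262682843928
24,0.00075984530099382219
25,0.0007843243318378379
26,0.0008111079708286173
27,0.00084041311731175572
28,0.00087247707026205656
29,0.0009075594441381174
30,0.00094594426412353272
31,0.00098794225744291975
32,0.0010338933589751909
33,0.0010841694510498323
34,0.0011391773591319376
35,0.0011993621270726118
36,0.0012652105977523087
37,0.0013372553272752441
38,0.0014160788634067778
39,0.0015023184216987895
40,0.0015966709957203618
41,0.0016998989410487164
42,0.0018128360761575646
43,0.0019363943471207845
44,0.0020715711071171983
45,0.0022194570661112634
46,0.0023812449708040528
47,0.0025582390800173993
48,0.002751865506101403
49,0.0029636834987605276
50,0.0031953977538747846
51,0.0034488718364658055
52,0.0037261428139075958
53,0.0040294372028131242
54,0.0043611883407119745
55,0.0047240553016439923
56,0.0051209434830854494
57,0.0055550270001291091
58,0.0060297730314772258
59,0.0065489682704503727
60,0.0071167476427316245
61,0.0077376254607418593
62,0.0084165291921585172
63,0.0091588360268235469
64,0.0099704124317691045
65,0.01085765688785667
66,0.011827546003003508
67,0.012887684195465932
68,0.01404635713532465
69,0.015312589122152165
70,0.016696204560626926
71,0.018207893672132158
72,0.019859282547414536
73,0.02166300760113149
74,0.023632794431173942
75,0.025783541011189959
76,0.028131405050463298
77,0.030693895237393409
78,0.033489965936902899
79,0.036540114733127904
80,0.039866481991048697
81,0.043492951347897102
82,0.047445249730165062
83,0.051751045117073735
84,0.056440039828133504
85,0.061544056592198859
86,0.067097114049280426
87,0.073135487635686336
88,0.07969775099993115
89,0.086824792185025257
90,0.094559797788598132
91,0.10294819717631276
92,0.11203755758260125
93,0.12187741960064069
94,0.13251906116674494
95,0.14401517672395936
96,0.15641945686597203
97,0.16978605250030021
98,0.18416890654420148
99,0.19962093552956939
100,1
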