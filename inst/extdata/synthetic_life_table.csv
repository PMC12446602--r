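age,q_male,q_female
0,3.4999387507173e-05,2.27496018796625e-05
1,3.82953666434593e-05,2.48919883182486e-05
2,4.19017298072255e-05,2.72361243746966e-05
3,4.58477047374783e-05,2.98010080793609e-05
4,5.01652711902834e-05,3.26074262736842e-05
5,5.48894200128602e-05,3.56781230083592e-05
6,6.00584365963996e-05,3.90379837876598e-05
7,6.57142110008779e-05,4.27142371505707e-05
8,7.19025772583093e-05,4.6736675217901e-05
9,7.86736845970193e-05,5.11378949880625e-05
10,8.60824035877616e-05,5.59535623320451e-05
11,9.4188770491388e-05,6.12227008194022e-05
12,0.000103058473397977,6.69880077086848e-05
13,0.000112763384080061,7.32961996520398e-05
14,0.00012338213985541,8.01983909060167e-05
15,0.000135000780148831,8.77505070967399e-05
16,0.000147713442889774,9.60137378783532e-05
17,0.000161623126355481,0.000105055032131063
18,0.000176842522597087,0.000114947639688107
19,0.000193494929157878,0.000125771703952621
20,0.000211715246417943,0.000137614910171663
21,0.000231651068583361,0.000150573194579184
22,0.000253463877083249,0.000164751520104112
23,0.000277330345952786,0.000180264724869311
24,0.000303443769669953,0.00019723845028547
25,0.000332015624882054,0.000215810156173335
26,0.000363277278520147,0.000236130231038095
27,0.000397481855947901,0.000258363206366136
28,0.000434906284058401,0.00028268908463796
29,0.000475853525595427,0.000309304791637027
30,0.000520655022479333,0.000338425764611566
31,0.000569673367538437,0.000370287688899984
32,0.000623305225826432,0.000405148396787181
33,0.000681984528627333,0.000443289943607766
34,0.000746185965355473,0.000485020877481057
35,0.000816428800829883,0.000530678720539424
36,0.000893281047884553,0.00058063268112496
37,0.000977364027957561,0.000635286618172415
38,0.00106935735522062,0.000695082280893405
39,0.00117000438296411,0.00076050284892667
40,0.0012801181543679,0.000832076800339138
41,0.00140058790348485,0.000910382137265153
42,0.00153238615624551,0.000996051001559584
43,0.0016765764855935,0.00108977471563577
44,0.00183432197948463,0.00119230928666501
45,0.00200689448545099,0.00130448141554315
46,0.00219568470076048,0.00142719505549431
47,0.0024022131828958,0.00156143856888227
48,0.00262814236115771,0.00170829253475251
49,0.00287528963665507,0.00186893826382579
50,0.00314564166479758,0.00204466708211843
51,0.00344136992162603,0.00223689044905692
52,0.00376484766291063,0.00244715098089191
53,0.00411866839286756,0.00267713445536392
54,0.00450566596756652,0.00292868287891824
55,0.00492893646655834,0.00320380870326292
56,0.00539186197486219,0.00350471028366042
57,0.00589813642611825,0.00383378867697686
58,0.00645179366627968,0.00419366588308179
59,0.00705723790552459,0.00458720463859099
60,0.00771927673387485,0.00501752987701865
61,0.00844315688303343,0.00548805197397173
62,0.00923460292284373,0.00600249189984842
63,0.0100998590850873,0.00656490840530672
64,0.0110457344095375,0.00717972736619937
65,0.0120796514066224,0.00785177341430454
66,0.0132096984269093,0.00858630397749107
67,0.0144446859189672,0.00938904584732868
68,0.0157942067428097,0.0102662343828263
69,0.0172687006847101,0.0112246554450616
70,0.0188795232890455,0.0122716901378796
71,0.0206390190820357,0.0134153624033232
72,0.0225605992084715,0.0146643894855065
73,0.024658823433097,0.0160282352315131
74,0.026949486370046,0.0175171661405299
75,0.029449707692986,0.0191423100004409
76,0.0321780259411631,0.020915716861756
77,0.03515449536753,0.0228504219888945
78,0.0384007850690872,0.0249605102949067
79,0.0419402793902736,0.0272611816036778
80,0.045798178290837,0.029768815889044
81,0.0500015960125189,0.0325010374081373
82,0.0545796559559365,0.0354767763713587
83,0.0595635791815906,0.0387163264680339
84,0.0649867633680804,0.0422413961892523
85,0.0708848483875884,0.0460751514519324
86,0.0772957638853298,0.0502422465254643
87,0.0842597533691254,0.0547688396899315
88,0.0918193683230246,0.059682589409966
89,0.100019424754126,0.0650126260901816
90,0.10890691336889,0.0707894936897787
91,0.11853085326643,0.0770450546231796
92,0.128942077653897,0.0838123504750333
93,0.140192938669579,0.0911254101352262
94,0.152336916996863,0.099018996047961
95,0.165428120644203,0.107528278418732
96,0.179520656158368,0.116688426502939
97,0.19466785477125,0.126534105601312
98,0.210921335736096,0.137098868228462
99,0.228329889616479,0.148414428250711
100,0.246938165832338,0.16050980779102
101,0.266785151678935,0.173410348591308
102,0.287902434707303,0.187136582559747
103,0.310312247225366,0.201702960696488
104,0.334025301212257,0.217116445787967
105,0.359038434596624,0.233374982487806
106,0.385332106043503,0.250465868928277
107,0.412867795411212,0.268364067017287
108,0.441585390946213,0.287030504115038
109,0.471400671797724,0.306410436668521
110,0.502203024767681,0.326431966098993
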