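"age","qx"
0,4.1520138015172e-05
1,4.54301784519329e-05
2,4.97084266294356e-05
3,5.43895547934214e-05
4,5.95114997423707e-05
5,6.51157701299088e-05
6,7.12477826809721e-05
7,7.79572300388942e-05
8,8.52984832165893e-05
9,9.33310319030101e-05
10,0.000102119966179592
11,0.00011173650353824
12,0.000122258565452227
13,0.000133771408151517
14,0.000146368312690104
15,0.000160151339864911
16,0.000175232156069405
17,0.000191732936729361
18,0.000209787354588875
19,0.000229541660793253
20,0.000251155867453057
21,0.00027480504118127
22,0.000300680717976287
23,0.000328992450787324
24,0.000359969502143564
25,0.000393862695377667
26,0.000430946439218149
27,0.000471520941887293
28,0.000515914632323478
29,0.000564486807758335
30,0.000617630528641722
31,0.000675775783813393
32,0.000739392950905415
33,0.000808996579217625
34,0.000885149524761819
35,0.000968467469840473
36,0.00105962386240854
37,0.00115935531360478
38,0.00126846749522236
39,0.001387841582557
40,0.0015184412920215
41,0.00166132056718593
42,0.0018176319714891
43,0.00198863585080422
44,0.00217571033432673
45,0.00238036224791716
46,0.00260423902006324
47,0.00284914166705397
48,0.00311703895076465
49,0.00341008280963806
50,0.00373062517100431
51,0.00408123626076962
52,0.00446472453470004
53,0.00488415836395939
54,0.00534288961616358
55,0.00584457928187454
56,0.00639322530504915
57,0.00699319278429533
58,0.00764924671965961
59,0.00836658748678953
60,0.00915088922633944
61,0.0100083413409826
62,0.0109456932948406
63,0.0119703029098861
64,0.0130901883501429
65,0.0143140839763588
66,0.0156515002401088
67,0.0171127877656647
68,0.0187092057388064
69,0.0204529946821314
70,0.0223574536440966
71,0.024437021761313
72,0.0267073640674288
73,0.0291854613136553
74,0.0318897034314567
75,0.0348399861023611
76,0.0380578096978322
77,0.0415663796075468
78,0.0453907066804466
79,0.049557706152064
80,0.0540962930157519
81,0.0590374713059729
82,0.0644144141898374
83,0.0702625310998204
84,0.0766195173777607
85,0.0835253810308565
86,0.0910224402196101
87,0.0991552840042327
88,0.107970687673754
89,0.117517472682187
90,0.127846299839842
91,0.139009382989973
92,0.151060108993687
93,0.164052548524092
94,0.178040841036691
95,0.19307843647381
96,0.209217175953672
97,0.226506194113838
98,0.244990627200202
99,0.264710113747952
100,0.285697079175361
101,0.307974802237494
102,0.331555270528111
103,0.356436844538572
104,0.382601765601056
105,0.410013562663991
106,0.4386144363646
107,0.468322726036699
108,0.499030595393285
109,0.530602104259124
110,1
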