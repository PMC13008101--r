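age	qx
0	5.49984875277687e-05
1	6.01777748489019e-05
2	6.58447871085821e-05
3	7.20454493923217e-05
4	7.88300105522e-05
5	8.62534501592238e-05
6	9.43759237325148e-05
7	0.000103263249843111
8	0.00011298744302346
9	0.000123627296783058
10	0.000135269021434459
11	0.000148006941870893
12	0.000161944260920865
13	0.000177193894426164
14	0.000193879384767559
15	0.00021213590018565
16	0.000232111327931439
17	0.000253967470027261
18	0.00027788135123441
19	0.000304046649715395
20	0.000332675261851989
21	0.000363999013735961
22	0.00039827153301264
23	0.000435770296013605
24	0.000476798866491657
25	0.000521689343767839
26	0.000570805039734057
27	0.000624543405927103
28	0.000683339233825686
29	0.00074766815362115
30	0.000818050458997632
31	0.000895055287936763
32	0.000979305192254865
33	0.00107148113149858
34	0.00117232792998712
35	0.00128266023921153
36	0.00140336905150029
37	0.00153542881485158
38	0.00167990520314176
39	0.00183796360054689
40	0.00201087836399338
41	0.00220004293278941
42	0.00240698086029134
43	0.00263335784854712
44	0.00288099487332882
45	0.00315188249382159
46	0.00344819644847183
47	0.00377231464609229
48	0.00412683566925542
49	0.00451459891523132
50	0.00493870650818651
51	0.00540254712497668
52	0.00590982188552647
53	0.00646457246736132
54	0.00707121161214586
55	0.00773455619988372
56	0.00845986307343261
57	0.00925286780185253
58	0.0101198265753758
59	0.0110675614269394
60	0.0121035089745795
61	0.0132357728747647
62	0.0144731801679748
63	0.0158253416833329
64	0.0173027166475235
65	0.0189166816128725
66	0.0206796037784203
67	0.0226049187237296
68	0.0247072125053626
69	0.0270023079772398
70	0.0295073550848093
71	0.0322409247448487
72	0.0352231057529605
73	0.0384756039538794
74	0.0420218426593953
75	0.0458870629980933
76	0.0500984225226587
77	0.0546850899759953
78	0.0596783336182025
79	0.0651115999336772
80	0.0710205788624524
81	0.0774432509242262
82	0.0844199107205655
83	0.0919931603060561
84	0.100207864811929
85	0.109111061490563
86	0.118751812038548
87	0.12918098667235
88	0.140450967010841
89	0.152615253417651
90	0.165727961151421
91	0.179843188570067
92	0.195014239877553
93	0.211292684671175
94	0.228727237074382
95	0.247362438807575
96	0.267237133495236
97	0.288382724224177
98	0.310821213291871
99	0.334563032681278
100	0.359604686530638
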