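"age","annual_death_prob"
60,0.011
61,0.0119477437479099
62,0.0129771436968836
63,0.0140952352245609
64,0.0153096598663243
65,0.0166287175409548
66,0.018061423275973
67,0.0196175688203509
68,0.0213077895656855
69,0.0231436372331998
70,0.0251376588233507
71,0.0273034823676164
72,0.0296559100685325
73,0.0322110194645352
74,0.0349862733110186
75,0.0380006389285809
76,0.0412747178341394
77,0.0448308865408713
78,0.0486934494892685
79,0.0528888051545068
80,0.0574456264653803
81,0.062395056767865
82,0.0677709226726129
83,0.0736099652410724
84,0.0799520910902625
85,0.0868406451323643
86,0.0943227068131516
87,0.102449411873888
88,0.111276301835754
89,0.120863703595333
90,0.131277141725489
91,0.142587786299472
92,0.154872939298894
93,0.168216562929889
94,0.182709853458225
95,0.198451864485186
96,0.215550183923995
97,0.234121669303522
98,0.254293246424671
99,0.276202776827825
100,0.3
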