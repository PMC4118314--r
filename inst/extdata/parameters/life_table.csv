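age,value,provenance
50,0.0021,placeholder
51,0.002302,placeholder
52,0.002524,placeholder
53,0.002767,placeholder
54,0.003034,placeholder
55,0.003327,placeholder
56,0.003647,placeholder
57,0.003999,placeholder
58,0.004384,placeholder
59,0.004806,placeholder
60,0.00527,placeholder
61,0.005777,placeholder
62,0.006334,placeholder
63,0.006944,placeholder
64,0.007614,placeholder
65,0.008347,placeholder
66,0.009152,placeholder
67,0.010034,placeholder
68,0.011,placeholder
69,0.012061,placeholder
70,0.013223,placeholder
71,0.014497,placeholder
72,0.015894,placeholder
73,0.017426,placeholder
74,0.019105,placeholder
75,0.020946,placeholder
76,0.022964,placeholder
77,0.025177,placeholder
78,0.027603,placeholder
79,0.030263,placeholder
80,0.03318,placeholder
81,0.036377,placeholder
82,0.039882,placeholder
83,0.043726,placeholder
84,0.047939,placeholder
85,0.052559,placeholder
86,0.057624,placeholder
87,0.063177,placeholder
88,0.069265,placeholder
89,0.07594,placeholder
90,0.083257,placeholder
91,0.091281,placeholder
92,0.100077,placeholder
93,0.109721,placeholder
94,0.120294,placeholder
95,0.131886,placeholder
96,0.144595,placeholder
97,0.158529,placeholder
98,0.173806,placeholder
99,0.190554,placeholder
100,0.208917,placeholder
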