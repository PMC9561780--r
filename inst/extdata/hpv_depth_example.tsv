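50	64
51	60
52	56
53	63
54	59
55	55
56	62
57	58
58	65
59	61
60	57
61	64
62	60
63	56
64	63
65	59
66	55
67	62
68	58
69	65
70	61
71	57
72	64
73	60
74	56
75	63
76	59
77	55
78	62
79	58
80	65
81	61
82	57
83	64
84	60
85	56
86	63
87	59
88	55
89	62
90	58
91	65
92	61
93	57
94	64
95	60
96	56
97	63
98	59
99	55
100	62
101	58
102	65
103	61
104	57
105	64
106	60
107	56
108	63
109	59
110	55
111	62
112	58
113	65
114	61
115	57
116	64
117	60
118	56
119	63
120	59
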