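roi_index	label	tissue	mrsn
1	Anterior salience region 1	GM	ASN
2	Anterior salience region 2	GM	ASN
3	Anterior salience region 3	GM	ASN
4	Anterior salience region 4	GM	ASN
5	Anterior salience region 5	GM	ASN
6	Anterior salience region 6	GM	ASN
7	Anterior salience region 7	GM	ASN
8	Auditory region 1	GM	AN
9	Auditory region 2	GM	AN
10	Auditory region 3	GM	AN
11	Basal ganglia region 1	GM	BGN
12	Basal ganglia region 2	GM	BGN
13	Basal ganglia region 3	GM	BGN
14	Basal ganglia region 4	GM	BGN
15	Basal ganglia region 5	GM	BGN
16	Dorsal default mode region 1	GM	DDMN
17	Dorsal default mode region 2	GM	DDMN
18	Dorsal default mode region 3	GM	DDMN
19	Dorsal default mode region 4	GM	DDMN
20	Dorsal default mode region 5	GM	DDMN
21	Dorsal default mode region 6	GM	DDMN
22	Dorsal default mode region 7	GM	DDMN
23	Dorsal default mode region 8	GM	DDMN
24	Dorsal default mode region 9	GM	DDMN
25	Higher visual region 1	GM	HVN
26	Higher visual region 2	GM	HVN
27	Language region 1	GM	LN
28	Language region 2	GM	LN
29	Language region 3	GM	LN
30	Language region 4	GM	LN
31	Language region 5	GM	LN
32	Language region 6	GM	LN
33	Language region 7	GM	LN
34	Left executive control region 1	GM	LECN
35	Left executive control region 2	GM	LECN
36	Left executive control region 3	GM	LECN
37	Left executive control region 4	GM	LECN
38	Left executive control region 5	GM	LECN
39	Left executive control region 6	GM	LECN
40	Posterior salience region 1	GM	PSN
41	Posterior salience region 2	GM	PSN
42	Posterior salience region 3	GM	PSN
43	Posterior salience region 4	GM	PSN
44	Posterior salience region 5	GM	PSN
45	Posterior salience region 6	GM	PSN
46	Posterior salience region 7	GM	PSN
47	Posterior salience region 8	GM	PSN
48	Posterior salience region 9	GM	PSN
49	Posterior salience region 10	GM	PSN
50	Posterior salience region 11	GM	PSN
51	Posterior salience region 12	GM	PSN
52	Precuneus region 1	GM	PN
53	Precuneus region 2	GM	PN
54	Precuneus region 3	GM	PN
55	Precuneus region 4	GM	PN
56	Primary visual region 1	GM	PVN
57	Primary visual region 2	GM	PVN
58	Right executive control region 1	GM	RECN
59	Right executive control region 2	GM	RECN
60	Right executive control region 3	GM	RECN
61	Right executive control region 4	GM	RECN
62	Right executive control region 5	GM	RECN
63	Right executive control region 6	GM	RECN
64	Sensorimotor region 1	GM	SMN
65	Sensorimotor region 2	GM	SMN
66	Sensorimotor region 3	GM	SMN
67	Sensorimotor region 4	GM	SMN
68	Sensorimotor region 5	GM	SMN
69	Sensorimotor region 6	GM	SMN
70	Ventral default mode region 1	GM	VDMN
71	Ventral default mode region 2	GM	VDMN
72	Ventral default mode region 3	GM	VDMN
73	Ventral default mode region 4	GM	VDMN
74	Ventral default mode region 5	GM	VDMN
75	Ventral default mode region 6	GM	VDMN
76	Ventral default mode region 7	GM	VDMN
77	Ventral default mode region 8	GM	VDMN
78	Ventral default mode region 9	GM	VDMN
79	Ventral default mode region 10	GM	VDMN
80	Visuospatial region 1	GM	VSN
81	Visuospatial region 2	GM	VSN
82	Visuospatial region 3	GM	VSN
83	Visuospatial region 4	GM	VSN
84	Visuospatial region 5	GM	VSN
85	Visuospatial region 6	GM	VSN
86	Visuospatial region 7	GM	VSN
87	Visuospatial region 8	GM	VSN
88	Visuospatial region 9	GM	VSN
89	Visuospatial region 10	GM	VSN
90	Visuospatial region 11	GM	VSN
91	Middle cerebellar peduncle	WM	WM
92	Pontine crossing tract	WM	WM
93	Genu of corpus callosum	WM	WM
94	Body of corpus callosum	WM	WM
95	Splenium of corpus callosum	WM	WM
96	Fornix (column and body)	WM	WM
97	Corticospinal tract R	WM	WM
98	Corticospinal tract L	WM	WM
99	Medial lemniscus R	WM	WM
100	Medial lemniscus L	WM	WM
101	Inferior cerebellar peduncle R	WM	WM
102	Inferior cerebellar peduncle L	WM	WM
103	Superior cerebellar peduncle R	WM	WM
104	Superior cerebellar peduncle L	WM	WM
105	Cerebral peduncle R	WM	WM
106	Cerebral peduncle L	WM	WM
107	Anterior limb of internal capsule R	WM	WM
108	Anterior limb of internal capsule L	WM	WM
109	Posterior limb of internal capsule R	WM	WM
110	Posterior limb of internal capsule L	WM	WM
111	Retrolenticular part of internal capsule R	WM	WM
112	Retrolenticular part of internal capsule L	WM	WM
113	Anterior corona radiata R	WM	WM
114	Anterior corona radiata L	WM	WM
115	Superior corona radiata R	WM	WM
116	Superior corona radiata L	WM	WM
117	Posterior corona radiata R	WM	WM
118	Posterior corona radiata L	WM	WM
119	Posterior thalamic radiation R	WM	WM
120	Posterior thalamic radiation L	WM	WM
121	Sagittal stratum R	WM	WM
122	Sagittal stratum L	WM	WM
123	External capsule R	WM	WM
124	External capsule L	WM	WM
125	Cingulum (cingulate gyrus) R	WM	WM
126	Cingulum (cingulate gyrus) L	WM	WM
127	Cingulum (hippocampus) R	WM	WM
128	Cingulum (hippocampus) L	WM	WM
129	Fornix (cres) / Stria terminalis R	WM	WM
130	Fornix (cres) / Stria terminalis L	WM	WM
131	Superior longitudinal fasciculus R	WM	WM
132	Superior longitudinal fasciculus L	WM	WM
133	Superior fronto-occipital fasciculus R	WM	WM
134	Superior fronto-occipital fasciculus L	WM	WM
135	Uncinate fasciculus R	WM	WM
136	Uncinate fasciculus L	WM	WM
137	Tapetum R	WM	WM
138	Tapetum L	WM	WM
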