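label_id	abbreviation	full_name	periventricular
1	MCP	Middle cerebellar peduncle	TRUE
2	PCT	Pontine crossing tract	FALSE
3	GCC	Genu of corpus callosum	TRUE
4	BCC	Body of corpus callosum	TRUE
5	SCC	Splenium of corpus callosum	TRUE
6	FX	Fornix	TRUE
7	CST-R	Corticospinal tract right	FALSE
8	CST-L	Cortical spinal tract left	FALSE
9	ML-R	Medial lemniscus right	TRUE
10	ML-L	Medial lemniscus left	TRUE
11	ICP-R	Inferior cerebellar peduncle right	FALSE
12	ICP-L	Inferior cerebellar peduncle left	FALSE
13	SCP-R	Superior cerebellar peduncle right	TRUE
14	SCP-L	Superior cerebellar peduncle left	TRUE
15	CP-R	Cerebral peduncle right	TRUE
16	CP-L	Cerebral peduncle left	TRUE
17	ALIC-R	Anterior limb of internal capsule right	TRUE
18	ALIC-L	Anterior limb of internal capsule left	TRUE
19	PLIC-R	Posterior limb internal capsule right	FALSE
20	PLIC-L	Posterior limb internal capsule left	FALSE
21	RLIC-R	Retrolenticular part of internal capsule right	TRUE
22	RLIC-L	Retrolenticular part of internal capsule left	TRUE
23	ACR-R	Anterior corona radiata right	TRUE
24	ACR-L	Anterior corona radiata left	TRUE
25	SCR-R	Superior corona radiata right	FALSE
26	SCR-L	Superior corona radiata left	FALSE
27	PCR-R	Posterior corona radiata right	TRUE
28	PCR-L	Posterior corona radiata left	TRUE
29	PTR-R	Posterior thalamic radiation right	FALSE
30	PTR-L	Posterior thalamic radiation left	FALSE
31	SS-R	Sagittal stratum right	TRUE
32	SS-L	Sagittal stratum left	TRUE
33	EC-R	External capsule right	TRUE
34	EC-L	External capsule left	TRUE
35	CGC-R	Cingulum right	FALSE
36	CGC-L	Cingulum left	FALSE
37	CGH-R	Cingulum (hippocampus) right	TRUE
38	CGH-L	Cingulum (hippocampus) left	TRUE
39	FX-ST-R	Fornix or stria-terminalis right	TRUE
40	FX-ST-L	Fornix or stria-terminalis left	TRUE
41	SLF-R	Superior longitudinal fasciculus right	FALSE
42	SLF-L	Superior longitudinal fasciculus left	FALSE
43	SFO-R	Superior frontal occipital fasciculus right	FALSE
44	SFO-L	Superior frontal occipital fasciculus left	FALSE
45	UNC-R	Uncinate fasciculus right	FALSE
46	UNC-L	Uncinate fasciculus left	FALSE
47	TAP-R	Tapetum right	TRUE
48	TAP-L	Tapetum left	TRUE
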