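index	name	x	y	z	hemisphere	label
1	superior frontal	-12.6	22.9	42.4	left	lSF
2	frontal pole	-8.6	61.7	-8.7	left	lFP
3	rostral middle frontal	-31.3	41.2	16.5	left	lRMF
4	caudal middle frontal	-34.6	10.2	42.8	left	lCMF
5	pars orbitalis	-41	38.8	-11.1	left	lPOB
6	lateral orbitofrontal	-24	28.6	-14.4	left	lLOF
7	pars triangularis	-42.4	30.6	2.3	left	lPT
8	pars opercularis	-44.6	14.6	13.1	left	lPOP
9	medial orbitofrontal	-8	34.9	-14.9	left	lMOF
10	rostral anterior cingulate	-6.8	33.9	1.6	left	lRAC
11	caudal anterior cingulate	-6.6	18	26.1	left	lCAC
12	insula	-34.2	-4.3	2.2	left	lINS
13	precentral	-37.8	-10.7	42.1	left	lPRC
14	postcentral	-42.3	-23.8	43.6	left	lPOC
15	supramarginal	-50.4	-38.8	31	left	lSUPRA
16	superior parietal	-22.8	-60.9	46.3	left	lSP
17	inferior parietal	-40	-66.4	27.3	left	lIP
18	paracentral	-10	-28.7	56.1	left	lPARAC
19	posterior cingulate	-7.3	-17.4	35.7	left	lPCG
20	isthmus cingulate	-8.9	-45.4	17.6	left	lIST
21	precuneus	-11.6	-57.5	36.7	left	lPREC
22	cuneus	-8.7	-79.6	18	left	lCUN
23	pericalcarine	-13.9	-80.6	6	left	lPERI
24	lingual	-16.5	-66.8	-4.3	left	lLIN
25	lateral occipital	-29.7	-86.9	-1	left	lLO
26	transverse temporal	-44	-24.2	6	left	lTRANS
27	banks superior temporal	-52.7	-44.5	4.6	left	lBKS
28	superior temporal	-52.1	-17.8	-4.4	left	lST
29	middle temporal	-55.6	-31.1	-12.9	left	lMT
30	inferior temporal	-48.9	-34.4	-22.2	left	lIT
31	temporal pole	-32.8	8.4	-34.8	left	lTP
32	entorhinal	-25.8	-7.6	-31.6	left	lENT
33	parahippocampal	-24.7	-31.2	-17.4	left	lPHIP
34	fusiform	-35.7	-43.3	-19.7	left	lFUS
35	superior frontal	13.4	24.7	42	right	rSF
36	frontal pole	10.3	61.1	-10	right	rFP
37	caudal anterior cingulate	7.3	18.7	26.3	right	rCAC
38	caudal middle frontal	34.9	11.8	43	right	rCMF
39	pars orbitalis	42.1	39.2	-10	right	rPOB
40	lateral orbitofrontal	23.6	28.5	-15.2	right	rLOF
41	pars triangularis	45	29.7	4.5	right	rPT
42	pars opercularis	44.9	14.4	14.2	right	rPOP
43	medial orbitofrontal	8.8	35.7	-14.8	right	rMOF
44	rostral middle frontal	32.3	40.9	17.3	right	rRMF
45	rostral anterior cingulate	8	33.5	2.1	right	rRAC
46	insula	35.1	-3.9	2.4	right	rINS
47	precentral	36.8	-9.9	43.5	right	rPRC
48	postcentral	41.6	-22.4	43.8	right	rPOC
49	supramarginal	50.6	-33.3	30.7	right	rSUPRA
50	superior parietal	22.6	-59.5	48.1	right	rSP
51	inferior parietal	42.8	-60.9	28.1	right	rIP
52	paracentral	9.9	-27.4	55.6	right	rPARAC
53	posterior cingulate	7.6	-17.1	36.2	right	rPCG
54	isthmus cingulate	9.8	-44.8	16.9	right	rIST
55	precuneus	11.7	-56.5	37.7	right	rPREC
56	cuneus	8.7	-80.1	19	right	rCUN
57	pericalcarine	14	-79.7	6.7	right	rPERI
58	lingual	16.8	-66.3	-3.6	right	rLIN
59	lateral occipital	30.3	-86.3	0.5	right	rLO
60	transverse temporal	44.8	-22.4	6.5	right	rTRANS
61	banks superior temporal	51.9	-40.6	5.6	right	rBKS
62	superior temporal	53	-14	-5.5	right	rST
63	middle temporal	55.9	-29.5	-12.9	right	rMT
64	inferior temporal	49.3	-31.7	-23	right	rIT
65	temporal pole	34	8.4	-33.1	right	rTP
66	entorhinal	26.2	-6.8	-31.9	right	rENT
67	parahippocampal	26.1	-31.3	-16.2	right	rPHIP
68	fusiform	35.9	-43	-19.2	right	rFUS
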