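region	measure	AD	DLB	difference	p
right posterior cingulate	strength	38.02	15.69	-22.33	<0.01
right posterior cingulate	triangles	1049.5	372.9	-676.6	0.03
right posterior cingulate	path length	1.8538	3.2901	1.4363	<0.01
right posterior cingulate	global efficiency of the nodes	0.5688	0.3494	-0.2194	<0.01
right posterior cingulate	clustering nodes	0.4747	0.2256	-0.2491	0.02
right posterior cingulate	closeness centrality	0.5394	0.3039	-0.2355	<0.01
left transverse temporal	degree	67	50	-17	<0.01
left transverse temporal	path length	2.0527	2.7779	0.7252	0.04
left transverse temporal	closeness centrality	0.4872	0.3600	-0.1272	0.02
left insula	degree	67	51	-16	<0.01
left superior parietal	degree	58	41	-17	<0.01
right transverse temporal	degree	67	52	-15	<0.01
right superior temporal	degree	67	52	-15	<0.01
right entorhinal	degree	67	40	-27	<0.01
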