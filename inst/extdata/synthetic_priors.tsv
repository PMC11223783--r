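pos	A	C	G	T
73	0.47	0.01	0.51	0.01
146	0.02	0.20	0.01	0.77
263	0.55	0.01	0.43	0.01
750	0.52	0.01	0.46	0.01
1438	0.49	0.01	0.49	0.01
2706	0.48	0.01	0.50	0.01
4769	0.51	0.01	0.47	0.01
7028	0.01	0.55	0.01	0.43
8860	0.52	0.01	0.45	0.02
15326	0.50	0.01	0.48	0.01
16189	0.03	0.25	0.01	0.71
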