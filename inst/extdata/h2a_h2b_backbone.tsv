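chain	number	reporter	pka_app	mc_sd	ci_lo	ci_hi	relation
H2A	55	H2A Q23	4.32	0.08	4.08	4.78	hb
H2A	89	H2A E91	5.51	0.11	4.37	6.07	hb
H2A	89	H2A L92	5.02	0.28	4.61	5.61	hb
H2A	91	H2B E102	4.36	0.06	3.89	4.79	hb
H2B	46	H2A G66	5.64	0.02	5.54	5.74	proximity
H2B	46	H2A N67	5.75	0.03	5.52	5.92	proximity
H2B	106	H2A A39	6.66	0.05	6.38	6.98	proximity
H2B	106	H2B Y80	6.80	0.17	5.56	7.96	proximity
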