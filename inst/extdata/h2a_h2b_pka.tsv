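chain	number	type	acidic_patch	predicted_dimer	predicted_nucleosome	sidechain_pka	sidechain_sd	sidechain_ci_lo	sidechain_ci_hi	sidechain_bound
H2A	55	GLU	TRUE	5.58	6.37	NA	NA	NA	NA	5
H2A	60	GLU	TRUE	5.18	5.56	NA	NA	NA	NA	5
H2A	63	GLU	TRUE	4.62	4.62	NA	NA	NA	NA	5
H2A	89	ASP	TRUE	3.42	3.88	NA	NA	NA	NA	NA
H2A	90	GLU	TRUE	4.45	4.82	NA	NA	NA	NA	5
H2A	91	GLU	TRUE	4.09	4.37	NA	NA	NA	NA	5
H2B	46	HIS	FALSE	6.13	6.43	5.86	0.03	5.66	6.06	NA
H2B	102	GLU	TRUE	3.79	3.59	NA	NA	NA	NA	NA
H2B	106	HIS	FALSE	6.72	6.53	6.52	0.05	6.23	6.93	NA
H2B	110	GLU	TRUE	3.45	4.55	NA	NA	NA	NA	NA
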