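snp_id	chrom_band	alleles	call_rate	p_hwe	maf_reference	maf_control	p_assoc
rs13387042	2q35	G>A	98.65	0.41	0.11	0.12	0.039
rs4973768	3p24.1	C>T	97.58	0.91	0.17	0.19	0.265
rs2307032	3p24.1	C>T	97.92	0.08	0.41	0.40	0.017
rs16886165	5p11.2	T>G	96.34	0.65	0.31	0.34	0.781
rs889312	5q11.2	C>A	98.31	0.23	0.50	0.48	0.595
rs4415084	5p12	A>G	96.12	0.03	0.46	0.43	0.798
rs10941679	5p12	G>A	97.19	0.95	0.57	0.50	0.768
rs2180341	6q22.33	A>G	97.30	0.49	0.22	0.26	0.040
rs2046210	6q25.1	G>A	98.48	0.50	0.35	0.34	1.26e-5
rs13281615	8q24.21	A>G	97.98	0.59	0.57	0.49	0.353
rs1562430	8q24.21	T>C	98.82	0.11	0.20	0.18	0.191
rs2981582	10q26.13	C>T	99.44	0.94	0.33	0.31	0.037
rs3817198	11p15.5	T>C	98.82	0.88	0.09	0.12	0.213
rs12443621	16q12.1	G>A	99.10	0.34	0.39	0.45	0.227
rs6504950	17q23.2	G>A	98.71	0.84	0.10	0.09	0.264
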