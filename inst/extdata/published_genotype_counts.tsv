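snp_id	chrom_band	position	major_allele	minor_allele	risk_allele	stage	status	hom_major	het	hom_minor
rs13387042	2q35	217614077	G	A	A	testing	case	627	223	12
rs13387042	2q35	217614077	G	A	A	testing	control	695	188	9
rs13387042	2q35	217614077	G	A	A	validation	case	712	181	16
rs13387042	2q35	217614077	G	A	A	validation	control	773	178	8
rs2307032	3p24.1	27407999	C	T	T	testing	case	265	436	160
rs2307032	3p24.1	27407999	C	T	T	testing	control	327	398	155
rs2307032	3p24.1	27407999	C	T	T	validation	case	288	429	195
rs2307032	3p24.1	27407999	C	T	T	validation	control	326	464	157
rs2180341	6q22.33	127642323	A	G	G	testing	case	423	373	54
rs2180341	6q22.33	127642323	A	G	G	testing	control	480	334	66
rs2180341	6q22.33	127642323	A	G	G	validation	case	479	380	51
rs2180341	6q22.33	127642323	A	G	G	validation	control	541	350	66
rs2046210	6q25.1	151990059	G	A	A	testing	case	290	413	158
rs2046210	6q25.1	151990059	G	A	A	testing	control	387	393	110
rs2046210	6q25.1	151990059	G	A	A	validation	case	292	460	155
rs2046210	6q25.1	151990059	G	A	A	validation	control	380	443	137
rs2981582	10q26.13	123342307	C	T	T	testing	case	362	400	110
rs2981582	10q26.13	123342307	C	T	T	testing	control	420	388	88
rs2981582	10q26.13	123342307	C	T	T	validation	case	370	420	106
rs2981582	10q26.13	123342307	C	T	T	validation	control	464	408	76
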