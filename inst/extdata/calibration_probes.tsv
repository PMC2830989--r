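probe	target	length	score_ratio	second_identity_pct	second_coverage_pct	masked_pct
Dusp6_5prime_probe	Dusp6_5prime	946	30.1	71	8	3.2
SAP102_5prime_PDZ3_probe	Dlg3_5prime	969	27.2	72	8	2.7
Dusp6_3prime_probe	Dusp6_3prime	1004	29.4	61	13	4.5
Actb_probe	Actb	881	22.8	91	6	6.7
SAP102_3prime_probe	Dlg3_3prime	886	22.2	77	8	19.4
NR2B_probe	Grin2b	567	11.1	81	14	9.5
SAP102_5prime_probe	Dlg3	784	9.89	68	29	81.7
PSD-95_exon_9_probe	Dlg4_exon9	296	3.3	76	54	nd
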