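chr	start_bp	end_bp	gvar_percent	top_snp	candidate_gene	distance
19	28728158	28766002	11.80	BovineHD1900008433	MYH10	within
24	30102158	30164301	10.30	BovineHD2400008151	CHST9	within
3	106567276	106628358	9.47	BovineHD0300030609	RLF	within
3	103471058	103518431	6.91	BovineHD0300029636	FAM183A	27683
2	98892271	98968329	4.95	BovineHD0200028465	CPS1	within
3	107082578	107188510	3.09	BovineHD4100002437	PABPC4	1629
3	105809585	105893206	1.92	BovineHD0300030334	CTPS	within
3	105103446	105151204	1.57	BovineHD0300030104	NA	NA
2	98767231	98852487	1.50	BovineHD0200028425	CPS1	within
12	37317791	37375872	1.36	BovineHD1200010822	ATP12A	395299
23	13141062	13228547	1.33	BovineHD2300003307	KCNK17	19569
26	28767232	28870785	1.33	BovineHD2600007699	SORCS1	377841
20	23511931	23646033	1.11	BovineHD2000007095	SLC38A9	within
12	37380083	37454520	1.08	BovineHD1200010844	NA	NA
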