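chr	start_bp	end_bp	gvar_percent	top_snp	candidate_gene	distance
3	106574782	106644015	20.15	BTB-00148396	RLF	within
21	5941998	5968820	10.77	BovineHD2100001150	ALDH1A3	108659
5	77160030	77212501	6.22	BovineHD0500021921	NA	NA
28	41315052	41343055	4.52	BovineHD2800011614	WAPAL	178111
5	77289332	77341198	2.90	BovineHD0500021954	NA	NA
3	103471058	103518431	2.79	BovineHD0300029636	FAM183A	27683
21	6031496	6114704	2.66	BovineHD2100001184	NA	NA
11	47195270	47279484	1.75	BovineHD1100013811	RPIA	24890
22	30689705	30734004	1.69	BovineHD2200008831	FOXP1	within
3	105080919	105138584	1.58	BovineHD0300030098	NA	NA
19	24496287	24525423	1.56	BovineHD1900007093	OR1G1	9771
24	36117632	36240233	1.50	BovineHD2400009926	ADCYAP1	within
3	79457216	79552102	1.31	BovineHD0300022907	PDE4B	within
20	23511931	23646033	1.26	BovineHD2000007095	SLC38A9	within
20	63943581	63965954	1.13	BovineHD2000018191	SEMA5A	204352
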