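chr	start_bp	end_bp	gvar_percent	top_snp	candidate_gene	distance
1	64788160	64867718	3.44	BTB-00033090	ARHGAP31	within
20	55978366	56002160	2.74	BovineHD2000015364	NA	NA
22	32826296	32856787	2.68	BovineHD2200009375	FAM19A4	within
4	18525619	18550135	2.62	BovineHD0400005535	C14H8orf59	424568
26	2272143	2343667	2.21	BovineHD2600000342	NA	NA
1	156048715	156119788	2.13	BovineHD0100045578	TBC1D5	within
9	86926509	86984196	2.06	BovineHD0900024383	SASH1	within
10	51554432	51726000	1.87	BovineHD1000015443	FAM63B	within
10	48374404	48406759	1.82	BovineHD1000014557	VPS13C	105944
25	25386519	25442136	1.77	BovineHD2500007181	KIAA0556	29783
9	93609823	93684438	1.72	BovineHD0900026491	NA	NA
23	19254288	19290469	1.64	BovineHD2300004888	CLIC5	within
14	49154187	49217544	1.54	BovineHD1400013993	MED30	195164
14	47765008	47835714	1.40	BovineHD1400013511	SAMD12	14727
5	18940413	19018750	1.39	BovineHD0500005477	DUSP6	336392
9	71346676	71377254	1.19	BovineHD0900019755	MOXD1	4746
25	30583072	30676658	1.16	BovineHD2500008480	NA	NA
3	60766989	60828010	1.15	BovineHD0300018250	TTLL7	317902
1	49845978	49930370	1.14	BTB-01076879	ALCAM	486294
21	38919896	39060313	1.13	BTB-00818234	NA	NA
9	88466483	88498915	1.01	BovineHD0900024910	PPP1R14C	within
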