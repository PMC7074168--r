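chr	start_bp	end_bp	gvar_percent	top_snp	candidate_gene	distance
10	64843548	64888989	7.89	BovineHD1000018698	SQOR	195750
18	46973033	47054361	6.52	BovineHD1800013865	TBCB	971
13	32898989	32942587	4.51	BovineHD1300009582	CACNB2	106042
17	59422381	59533974	4.23	BovineHD1700016840	WSB2	634
21	54246453	54304950	4.17	BovineHD2100015513	DYNLL1	49145
1	86864010	87000954	3.00	BovineHD0100024730	CCDC39	89435
18	43486335	43539576	2.83	BovineHD1800012856	CEP89	within
7	25274362	25344621	2.51	BovineHD0700006961	CHSY3	within
10	22200536	22227480	2.20	BovineHD4100007964	TRDC	within
21	18442926	18507549	2.06	BovineHD4100015053	NA	NA
18	9390632	9440030	1.78	BovineHD4100013431	CDH13	122107
16	55454686	55576782	1.57	BovineHD1600015438	BOVAGGRUS	12062
2	84272058	84486086	1.35	BovineHD0200024049	SLC39A10	461944
27	17515069	17628482	1.35	BovineHD2700005087	NA	NA
1	93966859	94071139	1.24	BovineHD0100026650	NLGN1	334630
20	58103188	58151048	1.14	BovineHD2000016087	ANKH	274075
22	21743429	21782083	1.14	BovineHD2200006300	ITPR1	within
3	83073814	83124751	1.07	BovineHD0300023782	ATG4C	225105
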