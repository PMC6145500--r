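id	locus	strand	sequence	length	count_MYC	count_PRI
cci-milR-1	Chr_1:2276359-2276380	+	CTGGATGGTGTGGGAGTTGCT	21	179	0
cci-milR-2	Chr_4:444870-444895	+	ACGAAGCAGTCGGCGCACTGGACGT	25	33	0
cci-milR-3	Chr_6:260570-260591	-	ATGAGCTCAGCGGTTATCCGAT	22	11	15
cci-milR-4a	Chr_7:1973680-1973700	+	TTTGCGGTGATGACTGACGT	20	1152	3469
cci-milR-4b	Chr_7:2383250-2383270	+	TCAGTCATCACCGCAAACCA	20	1143	4096
cci-milR-5-3p	Chr_9:6467-6488	-	TTCTTAGGAATATCGGCCAGAC	22	3.5	3
cci-milR-5-5p	Chr_9:6494-6515	-	CTTGGCACTCGGTCGATATTCC	22	6.5	3
cci-milR-6	Chr_9:2295986-2296004	-	CATCTGTCCTTCCCGCTGC	19	16	16
cci-milR-7	Chr_11:1942223-1942244	+	TCTTCCGAACCTCTTGATAGCT	22	25	25.5
cci-milR-8	Chr_12:1120052-1120072	-	CTGACTTCTGCCAGCCATTCT	21	33	29
cci-milR-9	Chr_12:1565625-1565643	+	TGCTTGGACTTCTATGGC	18	1379	1434
cci-milR-10	U377:434-457	-	GTGAAAAGACATAGAGGGTGTAGA	24	8925	2518
cci-milR-11	U382:2844-2863	-	GAAAAGTGACGGCTCATCCC	20	44	73.5
cci-milR-12a	U401:686-705	-	ATTGACACGGCTGGGCTTTT	20	14.5	16
cci-milR-12b	U401:1048-1069	+	TGAGTAGAATGGTCCCTGTCCC	22	220	232
cci-milR-12c	U401:4487-4512	-	GGCGCCGTTGAAATACCACTACCTTT	26	3724	50524
cci-milR-13a	U413:2349-2377	-	ATATTTGGTATTTGCGCCTGTCCGATCGG	29	2321	248
cci-milR-13b	U413:2422-2441	+	ATAACACTCCATCAGTAGGG	20	2	2
cci-milR-13c	U413:2964-2989	-	TGTGAAAAGACATAGAGGGTGTAGAA	26	9147	2863
cci-milR-13d	U413:3111-3130	-	CTAATTAGTGACGCGCATGA	20	6832	418
cci-milR-13e-3p	U413:3387-3405	-	ACCTCTAGATGGACCCCGC	19	900	823
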