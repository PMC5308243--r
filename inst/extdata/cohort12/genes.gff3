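##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-23
CSAB_NaTx1_locus	rtracklayer	gene	51	518	.	+	.	ID=CSAB_NaTx1;
CSAB_NaTx1_locus	rtracklayer	mRNA	51	518	.	+	.	ID=CSAB_NaTx1.t1;Parent=CSAB_NaTx1
CSAB_NaTx1_locus	rtracklayer	exon	51	168	.	+	.	Parent=CSAB_NaTx1.t1
CSAB_NaTx1_locus	rtracklayer	exon	259	518	.	+	.	Parent=CSAB_NaTx1.t1
CSAB_NaTx1_locus	rtracklayer	CDS	111	168	.	+	0	Parent=CSAB_NaTx1.t1
CSAB_NaTx1_locus	rtracklayer	CDS	259	458	.	+	2	Parent=CSAB_NaTx1.t1
CSAB_KTx1_locus	rtracklayer	gene	51	428	.	-	.	ID=CSAB_KTx1;
CSAB_KTx1_locus	rtracklayer	mRNA	51	428	.	-	.	ID=CSAB_KTx1.t1;Parent=CSAB_KTx1
CSAB_KTx1_locus	rtracklayer	exon	51	226	.	-	.	Parent=CSAB_KTx1.t1
CSAB_KTx1_locus	rtracklayer	exon	302	428	.	-	.	Parent=CSAB_KTx1.t1
CSAB_KTx1_locus	rtracklayer	CDS	111	226	.	-	2	Parent=CSAB_KTx1.t1
CSAB_KTx1_locus	rtracklayer	CDS	302	368	.	-	0	Parent=CSAB_KTx1.t1
CSAB_KTxB_locus	rtracklayer	gene	51	633	.	+	.	ID=CSAB_KTxB;
CSAB_KTxB_locus	rtracklayer	mRNA	51	633	.	+	.	ID=CSAB_KTxB.t1;Parent=CSAB_KTxB
CSAB_KTxB_locus	rtracklayer	exon	51	174	.	+	.	Parent=CSAB_KTxB.t1
CSAB_KTxB_locus	rtracklayer	exon	255	371	.	+	.	Parent=CSAB_KTxB.t1
CSAB_KTxB_locus	rtracklayer	exon	482	633	.	+	.	Parent=CSAB_KTxB.t1
CSAB_KTxB_locus	rtracklayer	CDS	111	174	.	+	0	Parent=CSAB_KTxB.t1
CSAB_KTxB_locus	rtracklayer	CDS	255	371	.	+	2	Parent=CSAB_KTxB.t1
CSAB_KTxB_locus	rtracklayer	CDS	482	573	.	+	2	Parent=CSAB_KTxB.t1
CSAB_KTx_UTR_locus	rtracklayer	gene	51	496	.	+	.	ID=CSAB_KTx_UTR;
CSAB_KTx_UTR_locus	rtracklayer	mRNA	51	496	.	+	.	ID=CSAB_KTx_UTR.t1;Parent=CSAB_KTx_UTR
CSAB_KTx_UTR_locus	rtracklayer	exon	51	75	.	+	.	Parent=CSAB_KTx_UTR.t1
CSAB_KTx_UTR_locus	rtracklayer	exon	146	265	.	+	.	Parent=CSAB_KTx_UTR.t1
CSAB_KTx_UTR_locus	rtracklayer	exon	351	496	.	+	.	Parent=CSAB_KTx_UTR.t1
CSAB_KTx_UTR_locus	rtracklayer	CDS	181	265	.	+	0	Parent=CSAB_KTx_UTR.t1
CSAB_KTx_UTR_locus	rtracklayer	CDS	351	436	.	+	2	Parent=CSAB_KTx_UTR.t1
CSAB_DFN_UTR_locus	rtracklayer	gene	51	608	.	-	.	ID=CSAB_DFN_UTR;
CSAB_DFN_UTR_locus	rtracklayer	mRNA	51	608	.	-	.	ID=CSAB_DFN_UTR.t1;Parent=CSAB_DFN_UTR
CSAB_DFN_UTR_locus	rtracklayer	exon	51	283	.	-	.	Parent=CSAB_DFN_UTR.t1
CSAB_DFN_UTR_locus	rtracklayer	exon	384	493	.	-	.	Parent=CSAB_DFN_UTR.t1
CSAB_DFN_UTR_locus	rtracklayer	exon	589	608	.	-	.	Parent=CSAB_DFN_UTR.t1
CSAB_DFN_UTR_locus	rtracklayer	CDS	111	283	.	-	2	Parent=CSAB_DFN_UTR.t1
CSAB_DFN_UTR_locus	rtracklayer	CDS	384	453	.	-	0	Parent=CSAB_DFN_UTR.t1
ICK_KTx1_locus	rtracklayer	gene	51	666	.	+	.	ID=ICK_KTx1;
ICK_KTx1_locus	rtracklayer	mRNA	51	666	.	+	.	ID=ICK_KTx1.t1;Parent=ICK_KTx1
ICK_KTx1_locus	rtracklayer	exon	51	189	.	+	.	Parent=ICK_KTx1.t1
ICK_KTx1_locus	rtracklayer	exon	255	279	.	+	.	Parent=ICK_KTx1.t1
ICK_KTx1_locus	rtracklayer	exon	420	666	.	+	.	Parent=ICK_KTx1.t1
ICK_KTx1_locus	rtracklayer	CDS	111	189	.	+	0	Parent=ICK_KTx1.t1
ICK_KTx1_locus	rtracklayer	CDS	255	279	.	+	2	Parent=ICK_KTx1.t1
ICK_KTx1_locus	rtracklayer	CDS	420	606	.	+	1	Parent=ICK_KTx1.t1
ICK_CAL1_locus	rtracklayer	gene	51	639	.	-	.	ID=ICK_CAL1;
ICK_CAL1_locus	rtracklayer	mRNA	51	639	.	-	.	ID=ICK_CAL1.t1;Parent=ICK_CAL1
ICK_CAL1_locus	rtracklayer	exon	51	294	.	-	.	Parent=ICK_CAL1.t1
ICK_CAL1_locus	rtracklayer	exon	415	436	.	-	.	Parent=ICK_CAL1.t1
ICK_CAL1_locus	rtracklayer	exon	507	639	.	-	.	Parent=ICK_CAL1.t1
ICK_CAL1_locus	rtracklayer	CDS	111	294	.	-	1	Parent=ICK_CAL1.t1
ICK_CAL1_locus	rtracklayer	CDS	415	436	.	-	2	Parent=ICK_CAL1.t1
ICK_CAL1_locus	rtracklayer	CDS	507	579	.	-	0	Parent=ICK_CAL1.t1
ICK_CAL2_locus	rtracklayer	gene	51	668	.	+	.	ID=ICK_CAL2;
ICK_CAL2_locus	rtracklayer	mRNA	51	668	.	+	.	ID=ICK_CAL2.t1;Parent=ICK_CAL2
ICK_CAL2_locus	rtracklayer	exon	51	186	.	+	.	Parent=ICK_CAL2.t1
ICK_CAL2_locus	rtracklayer	exon	247	271	.	+	.	Parent=ICK_CAL2.t1
ICK_CAL2_locus	rtracklayer	exon	422	668	.	+	.	Parent=ICK_CAL2.t1
ICK_CAL2_locus	rtracklayer	CDS	111	186	.	+	0	Parent=ICK_CAL2.t1
ICK_CAL2_locus	rtracklayer	CDS	247	271	.	+	2	Parent=ICK_CAL2.t1
ICK_CAL2_locus	rtracklayer	CDS	422	608	.	+	1	Parent=ICK_CAL2.t1
AMP_Kn1_locus	rtracklayer	gene	51	419	.	+	.	ID=AMP_Kn1;
AMP_Kn1_locus	rtracklayer	mRNA	51	419	.	+	.	ID=AMP_Kn1.t1;Parent=AMP_Kn1
AMP_Kn1_locus	rtracklayer	exon	51	180	.	+	.	Parent=AMP_Kn1.t1
AMP_Kn1_locus	rtracklayer	exon	253	419	.	+	.	Parent=AMP_Kn1.t1
AMP_Kn1_locus	rtracklayer	CDS	111	180	.	+	0	Parent=AMP_Kn1.t1
AMP_Kn1_locus	rtracklayer	CDS	253	359	.	+	2	Parent=AMP_Kn1.t1
PROT_ChTP1_locus	rtracklayer	gene	51	996	.	+	.	ID=PROT_ChTP1;
PROT_ChTP1_locus	rtracklayer	mRNA	51	996	.	+	.	ID=PROT_ChTP1.t1;Parent=PROT_ChTP1
PROT_ChTP1_locus	rtracklayer	exon	51	165	.	+	.	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	exon	254	348	.	+	.	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	exon	469	559	.	+	.	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	exon	655	745	.	+	.	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	exon	816	996	.	+	.	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	CDS	111	165	.	+	0	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	CDS	254	348	.	+	2	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	CDS	469	559	.	+	0	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	CDS	655	745	.	+	2	Parent=PROT_ChTP1.t1
PROT_ChTP1_locus	rtracklayer	CDS	816	936	.	+	1	Parent=PROT_ChTP1.t1
PROT_ChTP2_locus	rtracklayer	gene	51	923	.	-	.	ID=PROT_ChTP2;
PROT_ChTP2_locus	rtracklayer	mRNA	51	923	.	-	.	ID=PROT_ChTP2.t1;Parent=PROT_ChTP2
PROT_ChTP2_locus	rtracklayer	exon	51	276	.	-	.	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	exon	387	493	.	-	.	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	exon	594	715	.	-	.	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	exon	806	923	.	-	.	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	CDS	111	276	.	-	1	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	CDS	387	493	.	-	0	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	CDS	594	715	.	-	2	Parent=PROT_ChTP2.t1
PROT_ChTP2_locus	rtracklayer	CDS	806	863	.	-	0	Parent=PROT_ChTP2.t1
KUNITZ_PI1_locus	rtracklayer	gene	51	586	.	+	.	ID=KUNITZ_PI1;
KUNITZ_PI1_locus	rtracklayer	mRNA	51	586	.	+	.	ID=KUNITZ_PI1.t1;Parent=KUNITZ_PI1
KUNITZ_PI1_locus	rtracklayer	exon	51	171	.	+	.	Parent=KUNITZ_PI1.t1
KUNITZ_PI1_locus	rtracklayer	exon	250	339	.	+	.	Parent=KUNITZ_PI1.t1
KUNITZ_PI1_locus	rtracklayer	exon	432	586	.	+	.	Parent=KUNITZ_PI1.t1
KUNITZ_PI1_locus	rtracklayer	CDS	111	171	.	+	0	Parent=KUNITZ_PI1.t1
KUNITZ_PI1_locus	rtracklayer	CDS	250	339	.	+	2	Parent=KUNITZ_PI1.t1
KUNITZ_PI1_locus	rtracklayer	CDS	432	526	.	+	2	Parent=KUNITZ_PI1.t1
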