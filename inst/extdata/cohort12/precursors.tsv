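gene_id	signal_len	precursor_len	propeptide_spans	mature_spans
CSAB_NaTx1	19	85		19-85
CSAB_KTx1	22	60		22-60
CSAB_KTxB	21	90		21-90
CSAB_KTx_UTR	28	56		28-56
CSAB_DFN_UTR	23	80		23-80
ICK_KTx1	24	96	24-30	30-96
ICK_CAL1	22	92	22-28	28-92
ICK_CAL2	23	95	23-29	29-95
AMP_Kn1	23	58	36-58	23-36
PROT_ChTP1	18	150		18-150
PROT_ChTP2	20	150		20-150
KUNITZ_PI1	21	81		21-81
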