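GENES_OF_INTEREST	SASP factors and senescence genes of interest	CDKN1A	CDKN2A	TP53	SCAMP4	PAPPA	IGF1	IGF2	IGF1R	IGF2R	CSF3	CCL17	CCL19	CCL21	CX3CL1	IL6	CXCL8	AREG	CCL5	CXCL12	SPP1	HGF	MMP1	MMP2	MMP3	MMP10	MMP12	RARRES2	VEGFA	VEGFC	CCN2	SFRP2	WNT16	IL32	CSF1	IGFBP2	IGFBP3	IGFBP4	IGFBP5	IGFBP6	IGFBP7	SERPINE1	SERPINE2	TIMP1	TIMP2	COL1A1	CTSB	CCL2	IL11	DKK1	MIF	CD55	IL1A	IL1B	IL15	IL18	IL10	IL13	IL7	TNF	TNFRSF1A	TNFRSF1B	CXCL1	CXCL2	CXCL3	CXCL10	CXCL16	CCL3	CCL4	CCL8	CCL13	CCL20	CCL26	ICAM1	VCAM1	TNFRSF11B	PLAU	PLAT	LMNB1	EREG	FGF2	FGF7	HBEGF	NRG1	ANGPT1	ANGPTL4	PGF	KITLG	CSF2	LIF	OSM	STC1	GDF15	BMP2	BMP6	EDN1	FAS	PTGES	SELPLG	PLOD1	B2M	TIMP3	MMP9	MMP13	MMP14	EGF	FGF1
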