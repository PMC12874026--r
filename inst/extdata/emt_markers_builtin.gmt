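E	builtin epithelial markers (curated convenience list; replace with your preferred published set)	CDH1	EPCAM	KRT8	KRT18	KRT19	CLDN3	CLDN4	CLDN7	DSP	OCLN	TJP1	MUC1	ESRP1	ESRP2	GRHL2	OVOL1	OVOL2	CRB3	RAB25	ST14
M	builtin mesenchymal markers (curated convenience list; replace with your preferred published set)	VIM	FN1	CDH2	ZEB1	ZEB2	SNAI1	SNAI2	TWIST1	TWIST2	CXCR4	MMP2	MMP9	SPARC	COL1A1	COL1A2	COL3A1	COL5A1	FOXC2	ITGB1	TNC	SERPINE1	TGFB1	WNT5A	AXL
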