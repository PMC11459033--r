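cell_type	gene
B_cells	BLK
B_cells	CD19
B_cells	FCRL2
B_cells	MS4A1
B_cells	KIAA0125
B_cells	TNFRSF17
B_cells	TCL1A
B_cells	SPIB
B_cells	PNOC
CD45	PTPRC
CD8_T_cells	CD8A
CD8_T_cells	CD8B
Cytotoxic_cells	CTSW
Cytotoxic_cells	GNLY
Cytotoxic_cells	GZMA
Cytotoxic_cells	GZMB
Cytotoxic_cells	GZMH
Cytotoxic_cells	KLRB1
Cytotoxic_cells	KLRD1
Cytotoxic_cells	KLRK1
Cytotoxic_cells	PRF1
Cytotoxic_cells	NKG7
DC	CCL13
DC	CD209
DC	HSD11B1
Exhausted_CD8	CD244
Exhausted_CD8	EOMES
Exhausted_CD8	LAG3
Exhausted_CD8	PTGER4
Macrophages	CD163
Macrophages	CD68
Macrophages	CD84
Macrophages	MS4A4A
Mast_cells	MS4A2
Mast_cells	TPSAB1
Mast_cells	CPA3
Mast_cells	HDC
Mast_cells	TPSB2
Neutrophils	CSF3R
Neutrophils	S100A12
Neutrophils	CEACAM3
Neutrophils	FCAR
Neutrophils	FCGR3B
Neutrophils	FPR1
Neutrophils	SIGLEC5
NK_CD56dim_cells	KIR2DL3
NK_CD56dim_cells	KIR3DL1
NK_CD56dim_cells	KIR3DL2
NK_CD56dim_cells	IL21R
NK_cells	NCR1
NK_cells	XCL2
NK_cells	XCL1
T_cells	CD3D
T_cells	CD3E
T_cells	CD3G
T_cells	CD6
T_cells	SH2D1A
T_cells	TRAT1
Th1_cells	TBX21
Treg	FOXP3
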