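PW:FOCAL_ADHESION	Focal adhesion	VWF	IGF1R	CCND1	COL4A1	JUN	MAPK3	RAF1	IGF1	HGF	PTEN	FN1
PW:TOLL_LIKE_RECEPTOR	Toll-like receptor signaling pathway	FOS	TNF	JUN	MAPK3	IL12A	IL1B	STAT1
PW:P53_SIGNALING	p53 signaling pathway	CDKN1A	CCND1	GADD45G	IGF1	PTEN	GADD45A
PW:MAPK_SIGNALING	MAPK signaling pathway	FOS	TNF	JUN	GADD45G	MAPK3	RAF1	IL1B	GADD45A
PW:B_CELL_RECEPTOR	B cell receptor signaling pathway	FOS	CD19	JUN	MAPK3	RAF1
PW:ACUTE_MYELOID_LEUKEMIA	Acute myeloid leukemia	CCND1	MAPK3	PML	RAF1
PW:T_CELL_RECEPTOR	T cell receptor signaling pathway	FOS	TNF	JUN	MAPK3	RAF1
PW:CHRONIC_MYELOID_LEUKEMIA	Chronic myeloid leukemia	CDKN1A	CCND1	MAPK3	RAF1
PW:JAK_STAT	Jak-STAT signaling pathway	CCND1	SOCS3	IL12A	EPOR	STAT1
PW:CYTOKINE_RECEPTOR	Cytokine-cytokine receptor interaction	TNF	IL12A	IL1B	EPOR	HGF	CXCL12
PW:HEMATOPOIETIC_LINEAGE	Hematopoietic cell lineage	TNF	CD19	IL1B	EPOR
PW:ERBB_SIGNALING	ErbB signaling pathway	CDKN1A	JUN	MAPK3	RAF1
PW:NK_CYTOTOXICITY	Natural killer cell mediated cytotoxicity	PRF1	TNF	MAPK3	RAF1
PW:CELL_CYCLE	Cell cycle	CDKN1A	CCND1	GADD45G	GADD45A
PW:NOD_LIKE_RECEPTOR	NOD-like receptor signaling pathway	TNF	MAPK3	IL1B
PW:FC_EPSILON_RI	Fc epsilon RI signaling pathway	TNF	MAPK3	RAF1
PW:ECM_RECEPTOR	ECM-receptor interaction	VWF	COL4A1	FN1
PW:CHEMOKINE_SIGNALING	Chemokine signaling pathway	MAPK3	RAF1	STAT1	CXCL12
PW:GNRH_SIGNALING	GnRH signaling pathway	JUN	MAPK3	RAF1
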