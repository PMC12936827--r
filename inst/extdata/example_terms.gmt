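ANTIOXIDANT_DEFENSE	example term collection	SOD2	CAT	GPX1	PRDX1	HMOX1
ANGIOGENESIS	example term collection	ANGPT1	VEGFA	HBEGF	TEK	PGF	FGF2
INFLAMMATION	example term collection	CD40LG	IKBKG	IL6	TNF	CCL2	MARCO
ECM_REMODELING	example term collection	SPON2	MMP9	TIMP1	FN1
LIPID_METABOLISM	example term collection	DECR1	HAO1	APOA1	LPL	PCSK9
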