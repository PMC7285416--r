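SYNGO: regulation of protein polyubiquitination	SYNGO:0001	XIAP	UBE2D1	SKP2	CUL1	UBE2N	RNF4
SYNGO: regulation of cell proliferation	SYNGO:0002	SKP2	STAT1	PDPN	TNF	EGFR	MYC	CCND1	KRAS
SYNGO: response to cytokine stimulus	SYNGO:0003	STAT1	TNF	XIAP	IL6	IL1B	JAK2	SOCS3
SYNGO: regulation of inflammatory response	SYNGO:0004	TNF	NOS2	STAT1	PPARG	IL6	PTGS2	NFKB1
SYNGO: regulation of hormone levels	SYNGO:0005	PPARG	ACE	STK11	INS	LEP	ADIPOQ
SYNGO: fatty acid transport	SYNGO:0006	PPARG	CYP2A6	CD36	FABP4	SLC27A1
SYNGO: angiogenesis regulation	SYNGO:0007	ANGPT1	PDPN	ACKR3	VEGFA	TEK	FLT1
SYNGO: epithelial cell differentiation	SYNGO:0008	FOXA2	HOXA10	PDPN	KRT5	TP63	SOX2
SYNGO: small molecule metabolic process	SYNGO:0009	PPARG	STK11	CYP2A6	ACE	G6PC	PCK1	ACACA
SYNGO: negative regulation of apoptosis	SYNGO:0010	XIAP	TNF	STAT1	BCL2	MCL1	BIRC5
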