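source	target	polarity	relation_kind	provenance
PPARG	XIAP	-	regulation	curated literature relation
PPARG	UBE2D1	-	regulation	curated literature relation
PPARG	SKP2	-	regulation	curated literature relation
PPARG	ACKR3	-	regulation	curated literature relation
PPARG	MI21	-	regulation	curated literature relation
PPARG	HOXA10	-	regulation	curated literature relation
PPARG	STAT1	-	regulation	curated literature relation
PPARG	PDPN	-	regulation	curated literature relation
PPARG	MIR223	+	regulation	curated literature relation
PPARG	ANGPT1	+	regulation	curated literature relation
PPARG	CYP2A6	+	regulation	curated literature relation
PPARG	FOXA2	+	regulation	curated literature relation
LSCC	XIAP	+	disease_association	curated literature relation
LSCC	UBE2D1	+	disease_association	curated literature relation
LSCC	SKP2	+	disease_association	curated literature relation
LSCC	ACKR3	+	disease_association	curated literature relation
LSCC	MI21	+	disease_association	curated literature relation
LSCC	HOXA10	+	disease_association	curated literature relation
LSCC	STAT1	+	disease_association	curated literature relation
LSCC	PDPN	+	disease_association	curated literature relation
LSCC	MIR223	-	disease_association	curated literature relation
LSCC	ANGPT1	-	disease_association	curated literature relation
LSCC	CYP2A6	-	disease_association	curated literature relation
LSCC	FOXA2	-	disease_association	curated literature relation
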