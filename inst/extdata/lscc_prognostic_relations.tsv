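source	target	polarity	relation_kind	provenance
PPARG	TNF	-	regulation	curated literature relation
PPARG	NOS2	-	regulation	curated literature relation
PPARG	ACE	-	regulation	curated literature relation
PPARG	STK11	+	regulation	curated literature relation
TNF	LSCC	+	disease_association	curated literature relation
NOS2	LSCC	+	disease_association	curated literature relation
ACE	LSCC	+	disease_association	curated literature relation
STK11	LSCC	-	disease_association	curated literature relation
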