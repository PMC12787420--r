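gene	pathway
AKT1	Toll-like receptor signaling pathway
AKT1	C-type lectin receptor signaling pathway
AKT1	HIF-1 signaling pathway
AKT1	TNF signaling pathway
AKT1	FoxO signaling pathway
AKT1	JAK-STAT signaling pathway
AKT1	MAPK signaling pathway
AKT1	Adipocytokine signaling pathway
IL6	Toll-like receptor signaling pathway
IL6	C-type lectin receptor signaling pathway
IL6	HIF-1 signaling pathway
IL6	TNF signaling pathway
IL6	JAK-STAT signaling pathway
IL6	MAPK signaling pathway
TNF	Toll-like receptor signaling pathway
TNF	C-type lectin receptor signaling pathway
TNF	TNF signaling pathway
TNF	MAPK signaling pathway
TNF	Adipocytokine signaling pathway
EGFR	HIF-1 signaling pathway
EGFR	FoxO signaling pathway
EGFR	JAK-STAT signaling pathway
EGFR	MAPK signaling pathway
IL1B	Toll-like receptor signaling pathway
IL1B	C-type lectin receptor signaling pathway
IL1B	TNF signaling pathway
IL1B	MAPK signaling pathway
STAT3	HIF-1 signaling pathway
STAT3	JAK-STAT signaling pathway
STAT3	FoxO signaling pathway
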