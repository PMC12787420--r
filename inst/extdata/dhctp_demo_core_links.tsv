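compound	gene
curcumin	TNF
curcumin	IL6
curcumin	AKT1
curcumin	EGFR
curcumin	IL1B
Glycyrrhetic acid	TNF
Glycyrrhetic acid	IL6
Glycyrrhetic acid	AKT1
Glycyrrhetic acid	EGFR
Glycyrrhetic acid	IL1B
Tanshinone IIA	TNF
Tanshinone IIA	IL6
Tanshinone IIA	AKT1
Tanshinone IIA	STAT3
tenuifolin	TNF
tenuifolin	IL6
tenuifolin	AKT1
tenuifolin	EGFR
Albiflorin	TNF
Albiflorin	IL6
Albiflorin	AKT1
Albiflorin	IL1B
Paeoniflorin	TNF
Paeoniflorin	IL6
Paeoniflorin	AKT1
Paeoniflorin	STAT3
Salvianolic Acid B	TNF
Salvianolic Acid B	IL6
Salvianolic Acid B	AKT1
Liquiritigenin	TNF
Liquiritigenin	IL6
Liquiritigenin	AKT1
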