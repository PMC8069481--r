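patient	age	grade	er	pr	her2	subtype	relapse_months
BC01	48	1	+	+	-	Luminal A-like
BC02	70		-	-	+	HER2-enriched	6
BC03	39	2	+	+	-	Luminal A-like	45
BC04	47	2	+	+	+	Luminal B-like	61
BC05	70	2	+	-	-	Luminal A-like	59
BC06	29	1	+	+	-	Luminal A-like
BC07	36	2	+	+	-	Luminal A-like
BC08	47	2	-	-			24
BC09	72	2	+	-			23
BC10	27	2	-	-	-	Triple negative	107
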