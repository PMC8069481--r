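sample	lesion	biomarker	alteration	clone	ccf	classification
BC01	relapse	OncoKB	CDK4 amplification	1	1	trunk
BC01	relapse	OncoKB	ERBB2 mutation	5	0.522	branch
BC02	relapse	HRD	(HRD score >= 42)
BC03	relapse	OncoKB	BRCA2 mutation	4	0.943	branch
BC05	primary	OncoKB	PIK3CA mutation	1	1	trunk
BC05	relapse	OncoKB	PIK3CA mutation	1	1	trunk
BC05	relapse	OncoKB	IDH1 mutation	2	0.838	branch
BC05	relapse	OncoKB	ERBB2 amplification	2	0.838	branch
BC05	relapse	HRD	(HRD score >= 42)
BC07	primary	HRD	Bi-allelic BRCA2
BC07	relapse	HRD	Bi-allelic BRCA2
BC09	primary	OncoKB	ERBB2 amplification	2	0.554	branch
BC09	relapse	OncoKB	ERBB2 amplification	2	0.682	branch
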