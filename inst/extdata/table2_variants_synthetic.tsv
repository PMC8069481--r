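sample	lesion	gene	variant_class	origin	ref	alt	five_prime	three_prime
BC01	relapse	CDK4	other	somatic	C	T	A	G
BC01	relapse	ERBB2	missense	somatic	C	T	T	A
BC02	relapse	BRCA1	silent	somatic	T	C	A	A
BC03	relapse	BRCA2	nonsense	somatic	C	T	G	A
BC05	primary	PIK3CA	missense	somatic	G	A	C	T
BC05	relapse	PIK3CA	missense	somatic	G	A	C	T
BC05	relapse	IDH1	missense	somatic	C	T	T	T
BC05	relapse	ERBB2	other	somatic	A	G	C	C
BC05	relapse	WRN	frameshift	germline	C	A	T	G
BC07	primary	BRCA2	frameshift	germline	T	A	G	C
BC07	relapse	BRCA2	frameshift	germline	T	A	G	C
BC09	primary	ERBB2	other	somatic	G	C	A	T
BC09	relapse	ERBB2	other	somatic	G	C	A	T
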