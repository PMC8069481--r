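chrom	length	cen_start	cen_end	is_autosome
chr1	249250621	121535434	124535434	TRUE
chr2	243199373	92326171	95326171	TRUE
chr3	198022430	90504854	93504854	TRUE
chr4	191154276	49660117	52660117	TRUE
chr5	180915260	46405641	49405641	TRUE
chr6	171115067	58830166	61830166	TRUE
chr7	159138663	58054331	61054331	TRUE
chr8	146364022	43838887	46838887	TRUE
chr9	141213431	47367679	50367679	TRUE
chr10	135534747	39254935	42254935	TRUE
chr11	135006516	51644205	54644205	TRUE
chr12	133851895	34856694	37856694	TRUE
chr13	115169878	16000000	19000000	TRUE
chr14	107349540	16000000	19000000	TRUE
chr15	102531392	17000000	20000000	TRUE
chr16	90354753	35335801	38335801	TRUE
chr17	81195210	22263006	25263006	TRUE
chr18	78077248	15460898	18460898	TRUE
chr19	59128983	24681782	27681782	TRUE
chr20	63025520	26369569	29369569	TRUE
chr21	48129895	11288129	14288129	TRUE
chr22	51304566	13000000	16000000	TRUE
chrX	155270560	58632012	61632012	FALSE
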