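# Published per-sample dating inputs for the C11+D4 haplotype: chromosome
# counts, summed differences from the modal haplotype, and resampling-based
# effective sample sizes.
population	chromosomes	diff_total	ess
Combined	1013	822	19
CEU	165	110	13
GBR	178	136	14
FIN	180	160	10
TSI	193	105	18
IBS	28	24	9
PUR+MXL+CLM	231	249	16
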