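# Human-chimpanzee alignment summary for the C+D region and the published
# detection-power undercount factor.
d	l_aln	t_years	lineages	undercount_factor
1227	125531	6000000	2	1.58
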