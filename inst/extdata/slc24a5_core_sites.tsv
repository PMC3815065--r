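# 16 core-region SNPs (b37 region C). Positions are synthetic, evenly
# spaced placeholders within the block; published per-SNP coordinates are
# not shipped. Classification, network and dating results do not depend
# on them.
site_id	position	ancestral	derived	nickname	kind
rs1834640	48392000	G	A	c1	SNP
rs2675345	48397000	G	A	c2	SNP
rs2469592	48402000	G	A	c3	SNP
rs2470101	48407000	C	T	c4	SNP
rs938505	48412000	C	T	c5	SNP
rs2433354	48417000	T	C	c6	SNP
rs2459391	48422000	G	A	c7	SNP
rs2433356	48427000	A	G	c8	SNP
rs2675347	48432000	G	A	c9	SNP
rs2675348	48437000	G	A	c10	SNP
rs1426654	48442000	G	A	c11	SNP
rs2470102	48447000	G	A	c12	SNP
rs16960631	48452000	A	G	c13	SNP
rs2675349	48457000	G	A	c14	SNP
rs3817315	48462000	T	C	c15	SNP
rs7163587	48467000	T	C	c16	SNP
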