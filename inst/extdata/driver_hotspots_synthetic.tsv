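gene	chrom	pos	ref	alt	protein_change
TP53	chr2	2000050	A	T	p.R175H
ERBB2	chr1	1000050	A	T	p.L755S
KRAS	chr13	13000050	A	T	p.G12D
PIK3CA	chr14	14000050	A	T	p.E545K
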