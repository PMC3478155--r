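reference_id	position	ref_allele	alt_allele	region	ddg_reported
s0008	19	A	C	mature	-0.3
s0027-1	53	U	G	mature	-1.4
s0008	39	C	G	stem	2.2
s0009	41	U	C	stem	-0.5
s0015	48	C	A	stem	0.3
s0015	50	U	C	stem	-1.3
s0027-1	52	G	U	stem	0.6
s0007	43	G	A	stem	-0.1
mir-140	43	G	A	loop	0
s0007	39	A	C	loop	0
s0009	45	U	G	loop	0
s0013	40	C	U	anti-stem	2.7
s0013	41	A	G	anti-stem	1
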