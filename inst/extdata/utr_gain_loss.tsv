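accession	gene	snp_position	ref_allele	alt_allele	wild_mirna	snp_mirna	verdict
AB042609	C1rs-A	221	U	C	s0016-5p	-	Loss
AJ292212	cyp c 1.02	184	U	C	-	s0008-5p	Gain
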