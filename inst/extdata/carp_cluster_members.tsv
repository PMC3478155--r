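id	reference_id	start	end	strand
miR-212	CYC023A01I23/2	200	420	-
miR-132	CYC023A01I23/2	430	591	-
miR-430b-2	CYC084B02N10/1	362	530	-
miR-430c-2	CYC084B02N10/1	540	723	-
miR-430b-1	utg7180000000224	174	340	+
miR-430a	utg7180000000224	350	520	+
miR-430c-1	utg7180000000224	530	688	+
miR-430a-2	utg7180000000234	306	600	+
miR-430c-1-2	utg7180000000234	650	900	+
miR-430b-1-2	utg7180000000234	950	1206	+
miR-7	utg7180000001602	502	630	-
s0021	utg7180000001602	640	775	-
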