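metric	count
binding_sites	394
target_mrnas	206
mirnas_with_targets	83
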