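metric	count
raw_reads	11665437
cleaned_reads	7327921
other_srna	125827
repeat	18994
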