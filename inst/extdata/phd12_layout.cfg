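fwd_anchor = GCCTTGCTAGCG
rev_anchor = TCAGGTCACGTT
barcode_length = 3
left_border = TATTCTCACTCT
right_border = GGTGGAGGTTCG
insert_codons = 12
spacer_codons = 4
wt_amplicon_length = 381
anchor_min_length = 12
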