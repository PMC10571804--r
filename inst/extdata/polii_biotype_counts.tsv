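biotype	analyzed_n	altered_n
protein_coding	1734	72
lncRNA	201	36
antisense_lncRNA	49	6
snoRNA	8	1
miRNA	6	3
snRNA	7	1
pseudogene	3	1
tRNA	2	1
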