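chr1	0	200	0.50
chr1	200	500	-1.25
chr2	0	300	2.00
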