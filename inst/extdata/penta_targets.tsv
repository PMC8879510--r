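gene	target_seq
gabbr1a	GGATGTCCCTTGAGAACGGGAGG
gabbr2	GGCACGGCCTGGACAACAACTGG
necap1	GGAAGTTGGACGCTCCTGACTGG
tmem183a	GGTGTAGATTCGGGGAGAGGAGG
zgc103499	GGATCGGAAACCCACCAAGCAGG
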