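>gabbr1a
GGATGTCCCTTGAGAACGGGAGGGTGTCGCTG
>gabbr2
GGCACGGCCTGGACAACAACTGGTACGCG
>necap1
TCCAGTCAGGAGCGTCCAACTTCCAGTCCG
>tmem183a
CCTCCTCTCCCCGAATCTACACCCACT
>zgc103499
CCTGCTTGGTGGGTTTCCGATCCAGG
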