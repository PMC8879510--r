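gene	allele_id	allele_seq	published_label
gabbr1a	gabbr1a_del8	GGATGTCCCTTGAGGGTGTCGCTG	-8
gabbr1a	gabbr1a_cx2	GGATGTCCCTTGAGAAGGAGGGTGGGTGTCGCTG	+2 (-5, +7)
gabbr2	gabbr2_cx1	GGCACGGCCTGGACACGCGACTGGTACGCG	+1 (-3, +4)
necap1	necap1_del10	TCCGTCCAACTTCCAGTCCG	-10
necap1	necap1_del4	TCCAGGAGCGTCCAACTTCCAGTCCG	-4
tmem183a	tmem183a_del5	CCTCCCCGAATCTACACCCACT	-5
zgc103499	zgc103499_ins1	CCTGCTATGGTGGGTTTCCGATCCAGG	+1
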