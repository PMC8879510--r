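fish_id	gene	label
pentaKO1	gabbr1a	+2 (-2, +4)
pentaKO1	gabbr2
pentaKO1	necap1
pentaKO1	tmem183a	-5
pentaKO1	zgc103499
pentaKO2	gabbr1a
pentaKO2	gabbr2
pentaKO2	necap1	-4
pentaKO2	tmem183a
pentaKO2	zgc103499	-33
pentaKO3	gabbr1a	+2 (-2, +4)
pentaKO3	gabbr2	+1 (-2, +3)
pentaKO3	necap1
pentaKO3	tmem183a
pentaKO3	zgc103499
pentaKO4	gabbr1a
pentaKO4	gabbr2
pentaKO4	necap1	-10
pentaKO4	tmem183a
pentaKO4	zgc103499
pentaKO5	gabbr1a
pentaKO5	gabbr2
pentaKO5	necap1
pentaKO5	tmem183a	-5
pentaKO5	zgc103499
pentaKO6	gabbr1a	-8
pentaKO6	gabbr2
pentaKO6	necap1
pentaKO6	tmem183a
pentaKO6	zgc103499	+1
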