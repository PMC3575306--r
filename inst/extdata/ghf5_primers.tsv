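name	pattern	orientation	region	fixed_positions
CD1aF	CCICCITACGGICAATTGTC	forward	CD1	3,6,9,12,18
CD1bF	CCICCITATGGICAATTGTC	forward	CD1	3,6,9,12,18
CD1cF	CCICCITATGGICAATTATC	forward	CD1	3,6,9,12,18
CD1PraFa	CCGCCGTATGGGCAA	forward	CD1	3,6,9,12
CD1PraFb	CCTCCCTATGGCCAA	forward	CD1	3,6,9,12
CD1PraFc	CGCCGTATGGGCAA	forward	CD1	2,5,8,11
CD1MelF	CTCCATATGGGCAATTATCTGT	forward	CD1	2,5,8,11,17
CD2aF	CTCAAATGCAATTGGAACKC	forward	CD2	3,9,10,17
CD2bF	CTCAAATGCAATTGGAATKC	forward	CD2	3,9,10,17
CD2cF	CTTAAATGCAITTGGAATKC	forward	CD2	3,9,10,17
CD2dF	CTTAAATGCTITTGGAATKC	forward	CD2	3,9,10,17
ENG1	TAYGTIATCGTIGAYTGGCA	forward	ENG1	
ENG1R	TGCCARTCIACGATIACRTA	reverse	ENG1	
CD4aR	TCCACRTCCTGGGACCA	reverse	CD4	6,9,13
CD4cR	TCCACATCTTGGCACCA	reverse	CD4	6,9,13
ENG2	GTICCRTAYTCIGTIACRAA	reverse	ENG2	
CD6PraFb	TCTCCTACATCAACTGGGC	forward	CD6	
CD6aR	GCCCAGTTGGCGTAIGAGA	reverse	CD6	6,10,11,12,15,18
CD6bR	GCCCAITTGGCRTAIGAAA	reverse	CD6	6,10,11,12,15,18
CD6cR	GCCCAITTGAIGTAMGAAA	reverse	CD6	6,10,11,12,15,18
CD6dR	GCCCAGTTGAYGTAIGAGA	reverse	CD6	6,10,11,12,15,18
CDGp8R	GCCCAGTTGAGGTACGAA	reverse	CD6	6,10,11,12,15,18
CD6PraRa	CCCAGTTGGCGTAGGA	reverse	CD6	5,9,10,11,14
CD6MelR	TGTTTGAGATAGCCCAGTTG	reverse	CD6	17
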