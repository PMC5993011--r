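operon	regulated_gene	sigma	absolute_position	location	binding_sequence	evidence
acoABCL	acoA	SigL	1201	synthetic	TGGCACGGCTTTTGCA	synthetic fixture
levDEFG-sacC	levD	SigL	2402	synthetic	TGGCATGATATTTGCA	synthetic fixture
ptb-bcd-buk-lpdV-bkdAABB	ptb	SigL	3603	synthetic	TGGCACGCCGCTTGCA	synthetic fixture
rocABC	rocA	SigL	4804	synthetic	TGGCACGGTATTTGCT	synthetic fixture
rocDEF	rocD	SigL	6005	synthetic	TGGCATGCAACTTGCA	synthetic fixture
rocG	rocG	SigL		synthetic	TGGCACGATTTTTGCA	synthetic fixture
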