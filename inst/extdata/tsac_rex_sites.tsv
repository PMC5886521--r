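locus_tag	gene	product	category	sequence	distance
Tsac_0014		Cof-like hydrolase	Misc	TTGTAAATTTACATACTA	-65
Tsac_0416	adhE	AdhE	Carb	TTGTTAAATGAATAACAA	-150
Tsac_0416	adhE	AdhE	Carb	TTGTTAATAAATTAACAC	-31
Tsac_0648		Cation diffusion facilitator family transporter	Mem	ATGATAATCAATAATCTT	-116
Tsac_0675	echABCDEF-hypABFCDE	Energy-conserving Ni-Fe hydrogenase; Ni-Fe hydrogenase maturation factor	Energy	TTGTTAAATAATAAACAA	-138
Tsac_0692		Extracellular solute-binding protein family 1	Mem	TTGAAATTATTATTTCAA	-169
Tsac_0706	asrABC	Anaerobic sulfite reductase	Misc	TGGTTATTTATTTAACAAA	-56
Tsac_0744		Stage V sporulation protein T	Spo	TTGAACTTAAAATTTCAG	-36
Tsac_0924		ACT domain-containing protein	Syn	ATGATAATAAAACATCAA	-82
Tsac_0932		Stage II sporulation protein E	Spo	ATGATATAATCATATCAA	-37
Tsac_0989		Glutamyl-tRNA synthetase	Syn	ATGTATATGATAATACAA	-35
Tsac_1035		Translation initiation factor IF-1	Syn	AAGAAAAAATTGATTCAT	-154
Tsac_1163		ABC-type transporter, integral membrane subunit	Mem	ACGATATATGTAAATCAT	-92
Tsac_1375	marR	Regulatory protein MarR	Misc	CTGAAATAATCATTTCAA	-86
Tsac_1550	hfsABCD	Iron hydrogenases; sporulation protein	Energy	TTGTTAATAAATTAACTA	-78
Tsac_1619		Prephenate dehydrogenase	Carb	GTGATTTTAAATGATCAA	-10
Tsac_1753		3-oxoacyl-(acyl-carrier-protein) reductase	Syn	TTGATAAACTTTTATCCA	-35
Tsac_1856		PHP domain protein	Syn	TTGTTTTTAGTTTAACAT	-33
Tsac_1947		Fimbrial assembly family protein	Mem	ATGATTCAAAAAAATCAA	-186
Tsac_1985		ABC transporter related	Mem	TTGAATTGAAATTTTCTA	-82
Tsac_2078		ABC-2 type transporter	Mem	CTGATGAATTAAAATCAA	-99
Tsac_2087	adhA	Alcohol dehydrogenase AdhA	Carb	TAGTTAAATTTATAACAA	-34
Tsac_2115	rodA	Rod shape-determining protein RodA	Misc	TAGTATTATATCATACAA	-60
Tsac_2192		MutS2 protein	Syn	ATGAATTTTTGTATTCTT	-88
Tsac_2363	hydG	Fe-hydrogenase maturation protein	Energy	TTGTTAAATATTCAACAA	-92
Tsac_2550		Nucleoside-triphosphatase rdgB	Syn	ATGATTTTATTCAATCCT	-74
Tsac_2619		Gluconate 2-dehydrogenase	Carb	TTGATTACATAATATCCA	-44
Tsac_2652		Sigma 54 modulation protein/ribosomal proteinS30EA	Misc	ATGAAATCTAATATTCCT	-62
Tsac_2683		Phosphoribosyltransferase	Syn	AAGATTATTATCTATCAT	-165
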