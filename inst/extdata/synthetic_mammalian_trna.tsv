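# Synthetic elongator isoacceptor repertoire (48 members), modeled on the
# anticodon usage typical of mammalian genomes. Constructed for examples and
# tests; NOT an export of any database. Gene counts are illustrative.
amino_acid	anticodon	gene_count
Ala	AGC	23
Ala	CGC	5
Ala	GGC	2
Ala	UGC	9
Arg	ACG	7
Arg	CCG	4
Arg	CCU	5
Arg	UCG	6
Arg	UCU	6
Asn	GUU	27
Asp	GUC	15
Cys	GCA	28
Gln	CUG	18
Gln	UUG	10
Glu	CUC	8
Glu	UUC	12
Gly	CCC	6
Gly	GCC	14
Gly	UCC	9
His	GUG	10
Ile	AAU	14
Ile	GAU	2
Ile	UAU	5
Leu	AAG	10
Leu	CAA	7
Leu	CAG	9
Leu	UAA	6
Leu	UAG	3
Lys	CUU	16
Lys	UUU	13
Met	CAU	9
Phe	GAA	12
Pro	AGG	10
Pro	CGG	4
Pro	UGG	7
Ser	AGA	10
Ser	CGA	4
Ser	GCU	8
Ser	UGA	5
Thr	AGU	10
Thr	CGU	6
Thr	UGU	6
Trp	CCA	7
Tyr	GUA	13
Val	AAC	11
Val	CAC	16
Val	GAC	1
Val	UAC	5
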