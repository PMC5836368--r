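tx_id	gene_id	contig	strand	donor_end	acceptor_start	cum_nt	phase	boundary_residue	planted_kr	key
tx0001	gene0001	ctg0001	-	339	283	81	0	W	FALSE	ctg0001|-|339|283
tx0001	gene0001	ctg0001	-	202	154	163	1	I	FALSE	ctg0001|-|202|154
tx0002	gene0002	ctg0002	+	122	158	90	0	R	TRUE	ctg0002|+|122|158
tx0002	gene0002	ctg0002	+	247	296	180	0	Y	FALSE	ctg0002|+|247|296
tx0003	gene0003	ctg0003	-	333	298	85	1	K	TRUE	ctg0003|-|333|298
tx0003	gene0003	ctg0003	-	181	146	203	2	R	TRUE	ctg0003|-|181|146
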