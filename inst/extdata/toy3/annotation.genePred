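tx0001	ctg0001	-	25	420	39	420	3	25,202,339,	155,284,420,	0	gene0001	cmpl	cmpl	-1,-1,-1,
tx0002	ctg0002	+	25	379	33	377	3	25,158,296,	123,248,379,	0	gene0002	cmpl	cmpl	-1,-1,-1,
tx0003	ctg0003	-	25	427	50	418	3	25,181,333,	147,299,427,	0	gene0003	cmpl	cmpl	-1,-1,-1,
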