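tx_id	gene_id	protein
tx0001	gene0001	MGQSSSLAFSMYRWPAMRRVMGPISPWTYIRCAPAIDPIFLALINQYRVKALIIIIMAYTLIPRVSASAVGVWGRTQFFPKRPELPLGITRT
tx0002	gene0002	MQRAISPFPYLDDSFRGKSRLCENERSLFRKSIKDWIVRPACSGLKMRRGGASALRNQTYKHGRIMPPNNGNLYIWDCRGRVADRR
tx0003	gene0003	MGLVAKYYRRECTFGWNQTSTSEALLPLKDGQRNVFAEVYARRLTVLGSKMQTCGLLFGVLVYGCASRYRHAATARLTSLHVPQHVRTYQSSNPTLCVT
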