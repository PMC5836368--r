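>ctg0001
GTTAAAGGGCCGCGGTCTATTCGAAAAACTACACTCCGGCTAGGTTCGGGTTATGCCCAAAGGAAGCTCG
GGACGCTTTGGGAAAAATTGGGTTCTCCCCCAAACACCAACTGCAGACGCGCTTACTCTCGGAATTAACG
TGTAAGCCATAATAACTGTCCAAAAGTCGTCAGGGGCTTAAGACTGAAGGGTGGCTCGAAACTTATAATG
AGAGCCTTGACTCGGTATTGGTTAATGAGAGCTAAGAATATGGGATCAATAGCCGGAGCGCACCGAATAT
ATGTCTAGGTTAGGTAGGTGTGCGTTGTTAAGTGGCCATCATTCGTTTTTAATGGCCACCCATGGCGATA
TAGGACCCATTACCCGTCTCATCGCTGGCCAGCGGTACATGGAGAAGGCTAGGCTAGAGGATTGACCCAT
ACATCCTCGGTAAGCACCCCTTCCC
>ctg0002
CTTTTAAGATGCACGGACGTCAACGGGCGTTAGATGCAACGTGCGATTTCGCCCTTCCCTTATCTCGATG
ACAGCTTCAGAGGCAAGTCTCGACTATGCGAGAATGAACGGTCCCTATTCCGTGTTCCAAGGTGAGGCAA
CCTTCATTTATTAGTCAGAAAAGCATTAAAGACTGGATCGTAAGACCAGCCTGTTCGGGACTTAAGATGC
GCCGAGGGGGGGCATCAGCCCTACGAAACCAAACATATGTGTTCCGTAGCCGAATACACCATCCGCCGAC
ATCGGATCCCGATTAGAAACATGGACGTATTATGCCGCCTAACAACGGCAATCTTTACATTTGGGACTGC
CGCGGGAGAGTGGCGGACCGTAGATGACAACCCGATATCAGATATTCTGTCCCG
>ctg0003
AAATGAGACGCTATAGTCAACAGTTCCGGGTCCCGAGTAAGTTTGCCGCATTATGTAACACACAAAGTTG
GGTTTGAGGACTGGTAGGTGCGTACGTGCTGAGGTACATGGAGTGAGGTTAAACGTGCTGTGGCGGCATG
TCTATAGCTATGCTTAGATTCTTTCGGCGCATCTCGCTAACCGGGACGCGCATCCGTACACGAGGACGCC
AAACAAGAGTCCACATGTTTGCATTTTAGAACCCAGGACTGTTAGCCTCCGCGCATATACTTCTGCAAAC
ACATTCCTTTGACCATCCTCTAAGGTCACGTCTAGGATTGAAACCAGACTGACTTAAGGGCAGTAAGGCT
TCAGATGTTGAGGTTTGGTTCCATCCGAAAGTGCACTCGCGTCTGTAATACTTGGCCACAAGACCCATGT
CCCTACTCTAAAGTTGATAGGCGAATATCGTA
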