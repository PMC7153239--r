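>RNA5S 5S rRNA, full length 121 nt
GTCTACGGCCATACCACCCTGAACGCGCCCGATCTCGTCTGATCTCGGAAGCTAAGCAGG
GTCGGGCCTGGTTAGTACTTGGATGGGAGACCGCCTGGGAATACCGGGTGCTGTAGGCTT
T
>RNA5-8S 5.8S rRNA, full length 157 nt
CGACTCTTAGCGGTGGATCACTCGGCTCGTGCGTCGATGAAGAACGCAGCTAGCTGCGAG
AATTAATGTGAATTGCAGGACACATTGATCATCGACACTTCGAACGCACTTGCGGCCCCG
GGTTCCTCCCGGGGCTACGCCTGTCTGAGCGTCGCTT
>RNA28S-5prime 28S rRNA 5'-terminal excerpt, first 27 nt only
CGCGACCTCAGATCAGACGTGGCGACC
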