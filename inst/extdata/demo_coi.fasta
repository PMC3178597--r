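>coi_sp01_1
TTTACACTTAGGCGCGCATGAATGACTCTAGCGAAACTTCTTTGGAACACAGTCGGCGGCCTGCCTAAAA
GTCTTTGTGGAACGGAATCTCACGGAAAGAAATTATCATCTTATCTAGCGTCCAATTGACGCTAGTGTGA
TACCCCCTAACCCTGGTAGCCATAGAATAGCCAATCCTCCTGCTAGCAACGCTATTTCCTGTTGCCCCCT
TTCTTGCCCTAGCTAAGTGGACCCGTATTTCTCTTTTTAAGTCTCGAATGTGTGAAAGGAATGCAGGTGG
TCAACTGAATCGGCTCGCAA
>coi_sp01_2
TTTACACTTAGGCGCGCATGAATGACTCTAGCGAAACTTCTTTGGAACACAGTCGGCGGCCTGCCTAAAA
GTCTTTGTGGAACGGAATCTCACGGAAAGAAATTATCATCTTATCTAGCGTCCAATTGACGCTAGTGTGA
TACCCCCTAACCCTGGTAGCCATAGAATAGCCAATCCTCCTGCTAGCAACGCTATTTCCTGTTGCCCCCT
TTCTTGCCCTATCTAAGTGGACCCGTATTTCTCTTTTTAAGTCTCGAATGTGTGAAAGGAATGCAGGTGG
TCAACTGAATCGGCTCGCAA
>coi_sp02_1
TTTACACTTAGGCGCGCATGAATGACTCTAGCGAAACTTCTTTGGAACACAGTCGGCGGCCTGCCTAAAA
GTCTTTGTGCAACGGAATCCCACGGAAAGAACTAATCATCTTATCTAGCGTCCAATTGTCGCTAGTTTGA
TACCCCCTAACCCTGGTAGCCCTAGAATAGCCAATACTCCTGCTAGCAACGCTATTTCCTGTTGCCCCCT
TTCTGGCCCTATCCACGTGGACCCGTATTTCTCCTTTTAAGGCTCGAATGTGTGAAAGGAATGCAGGTGG
TCGACTGAATCAGCTCGCAA
>coi_sp02_2
TTTACACTTAGGCGCGCATGAATGACTCTAGCGAAACTTCTTTGGAACACAGTCGGCGGCCTGCCTAAAA
GTCTTTGTGCAACGGAATCTCACGGAAAGAACTAATCATCTTATCTAGCGTCCAATTGTCGCTAGTTTGA
TACCCCCTAACCCTGGTAGCCCTAGAATAGCCAATACTCCTGCTAGCAACGCTATTTCCTGTTGCCCCCT
TTCTGGCCCTATCCACGTGGACCCGTATTTCTCCTTTTAAGGCTCGAATGTGTGAAAGGAATGCAGGTGG
TCGACTGAATCAGCTCGCAA
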