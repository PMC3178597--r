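>its_sp01_1
AAAACTCCATGTGTAACTCCGGAAGTAGAATGTTGCACTCGGCCCGTCCATATCTCGTGAACCCCCTGCA
CGCCCTAAAGTACAATTAGGATATTCATCCATACACTGTATATGCCGAACGTTCTAATAAACGACGTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGCATTTCACGCCTCCCGCTTGCCGTCTTCAACGTCATGACCCT
CGTGTATCACAAAGCCACAAGCCGGATTCTAGGCTTTGAAACAGCTGAATAATCCGTGTGAATCCGCTAG
TCGTCGGAAAGCAGTTGAAT
>its_sp01_2
AAAACTCCATGTGTAACTCCGGAAGTAGAATGTTGCACTCGGCCCGTCCATATCTCGTGAACCCCCTGCA
CGCCCTAAAGTACAATTAGGATATTCATCCATACACTGTATATGCCGAACGTTCTAATAAACGACGTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGCATTTCACGCCTCCCGCTTGCCGTCTTCAACGTCATGACCCT
CGTGCATCACAAAGCCACAAGCCGGATTCTAGGCTTTGAAACAGCTGAATAATCCGTGTGAATCCGCTAG
TCGTCGGAAAGCAGTTGAAT
>its_sp02_1
AAAACCCCATGTGTAACTCCGGAAGTAGATTCTTGCACTCGGCCTTTCCATATCTCGTAAACCCCCAGCA
CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATACACGCCTTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGTATGTCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT
CGTGCATCACAAAGCCTCAAGGCGGAGTCTAGGCTTTGAAACAGCTGAATGATTCGCGTGAATACGAGAG
TCCTCCGAAAGCAGTTGAAT
>its_sp02_2
AAAACCCCATGTGTAACTCCGGAAGTAGATTCTTGCACTCGGCCTTTCCATATCTCGTAAACCCCCAGCA
CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATAAGCCGAACGTTCTAATACACGACTTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGAATGTCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT
CGTGCATCACAAAGCCTCAAGGCGGAGTCTCGGCTTTGAAACAGCTGAATGATTCGTGTGAATACGAGAG
TCCTCCGAAAGCAGTTGAAT
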