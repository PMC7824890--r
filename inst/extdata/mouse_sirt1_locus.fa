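>mm10_synth
TCCAGTGCACTAGACGCCGGGTGGATATGACGAAGGCTTATTCTTGGTTAGTCTAACGCCAGCACCCCGT
CGTTAGTGCGAGGGCCCGGTCCCTACGTCATTAATGACCTTTAACATCAGTAGCAGAAGTAGCATATTTA
TGCAGAACAAAATTACCCATAAACAGACCAACCCAAACTTCTTTACCACAAATATGTTTATTAAATTGTT
GATCAACATTAGTTTGAATAACTTCTTCAAATTCCATAATATTCAGCATACCACAAGAAGGAACAGAAAT
AATACGAGGGAGTGAAGATATTCTTGCAGCGTGACGCCCGTAGACCGCTTGCTGCCCGGAGATTGTTAGG
CGACGTGCTATTGGCGAGTGAGGAGTTTGAGTGAATAAAAAAGACGCAGGATGCGATCGCAAAACCACGT
TCTGTCCTTCATTGCTATAACACGATACAGACGTTCAACAGCCATCCAATAATTACGAAACATATACATA
TGATTAGGATAAAAATTATTATAAACACAACAATTCAGTTCATCAATAAAATGAGTAACAATTTGATGTT
TAGTAGATCCGTGGACGTAGTCCTCGGACCAGTTCGTCAGTACGTACTAGGGTCACTACTAACTATACAG
CCGCAACCATCAAAATATCCAGCTTGACAATCATAATGAATATTAGTAACAATTTTAAAATCCATATCCA
TAGGAGGAGAAGCTTCAGGCATAATCCAATGATGAAATTCATGATTAGCACCAGCATTAGCCAGAGCCCA
AACATGAGCATGTTTACAACCAGTATACAGCCTCAATACTTCAACGAAAGATGAGGCGAAAAACCCGTCC
CAGCCCTAGAGCGAAATAGTGTGCAATTAGAGAACAACTTGACGCAACTTTGAAAATGATTGTCGAGCAC
CGCCGCCACTTAACTATCCAGAATTAACAAAGATTCAGTTTCAATATAACCAACCCAACCAGGACGATAC
ATAGAAAAATGTTTCAGAACACAAGAAGGCATAGTACCTTGCAGAGACCAAAAAATCAGAGGATCAGTCC
ACCAACCCAGAGCATACCAAACATTTTGACCAGCTTCAACTGTGCGCAAGGATTGAGCTGCCTAGCTCGC
GATGGGTTGCCTCATAAGCGCACTAGCTACTTAACGTTTATTCCACTACAGAGAATGTTTCAGCAGAAAT
TTAAAAACAACACACAGACAATGCATATCAAAAGCACCAGTAACAACAGAAGCACCATGTTTAGATTTAC
AATTACGAATCCAAACTTGATTAATAGATTCATGATTATATTCTTCAGTCCAATGAGCATCTTGGAATCA
ATCCGTAAACGTAGTTTAAGCTTTGATGGATCTCTCGTGTCCCGTCACTCAGAGCGTATGGACAAGGCTG
AACCTGTTGTGCGTGGCAATATGATCCTTCTCCCTGGGGCCCGACGGAGGTCCAACTTTAGGAGAAGAAA
AACGTTCAGGATGAATACGATGACAAGACAGAGATTGAATATTACACAGATCACATTCTTTCAGAGTATT
CAGCCAACAATTATGAATAACAGACCAACCACGCAGACACTGATTCTTTTGACAGACAGGCAGGATCATA
TGTGACAATCTAAGCTCTTGCGAGAAAGAGCCCGAACCCATCCTATCCCTCCAAGAAGATGCCATTTTGG
CACGAAATAACCATCAGTTACCAGAAACATCACGACGCAGTTTAGATTGACAATCACCTTGAGGCAGACA
ACAAGGATGCCACATAATATAATTAATTTTACGTTTAGCAGATTTAGCAGGCAGAACAGGATGAGTATAA
ACATAAGGCAGAGGTTGCATAGAGAGATGATAGATGAAAAGAACCGCCGTTCAAGCCTCGAATAGTAATC
TGGTGTGCGGCGTCGAGATGTATGAACACTTACCTTAAACGTCTGCTCCAGTCAATAAATTGGAGATGGA
CTCTAAAGGCTCACGTTCATATTCCAGAGTAACATTACAAGCTTTAGTACAATCATTACAAGCTTCTTTT
TTATAAATATTCCAAGTACGAGTACGAGCAATACCAGGTTCATGTTCCATAGTAATATCACATTCACGAG
TATAATAATCGGGTCTTATGCAGTAGGAGTGGGCTGACTCTATGAACGCTTCGCGGTTAAGCACCCTAGT
ACCGCCGCCGAATAGAAACATTCCAAGCAAACATCATAACAATATTATATTGTTTCCAATATTCTTTAAC
TTTCAGAACCCACATACAACAATAAGCATAATGAGAAAAAACAGAACATTGACCAAAAGGTTTACGTTTA
GCAGATTTAGCAGGAACTTTACAACCCCATTTACAAGTTTCATACCACTCACGCTTGACGGATGCCTAGA
GGAAGGGCCAGGATAACGATTGGCCCCTGACAAGACCCCTTCGCCCCACGGTTGTGGCGCCTGTGAATCG
GCGCAAC
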