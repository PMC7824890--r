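>hs10_synth
TCCGTTAGCTGCGCAACTACTCTGTTTGGCCGTTTACACGGAAGATCCAGGTGGACCGCAGTCCCTATAT
TGGCTATTTCGTTATTCTTGGCCAAGTAACAAACAAGATCATGAAGCTCAAAAATATCCTGCTAAATCTG
CTAAACGTAAATGTTCTTGTGAAGTTATTGTTCATTTTTGGATTACTAATAAATCTTGTATTACTCCTCT
GGTTTGGCAACATAATCCTCGTTATTTTCCTCCTAAATCTTGTCCTGCTTTTGCTATTACTTCTCAATAT
CTGATATATGCTATACGTGCCATCGTATATCATAATTTCTTATACCTCCGCGGCTCTACAATAAGTGCTC
TAAGAGGGCGGCAAGCACATTTCGTCATAAAGCTCTGCTGATTATGTGGGAAACTGAATGGGATATGTCT
ATTGAAGCTCGTACACAGGCTTGACTGGTGCTTAGTGTAGCTAGTTCTGTGCTCCAGATGCCTTCTCTAG
TAGTAGCAGTAGTATTACGTCGCGAGAATTACACTACCTGTTAAAAATGCTGGTTTCTGGTAATCCTAAT
CTGGATAAAGATAAAGAATGGTGTCGTTGTCCTTGGTGGACTCTGGGTGAATGGTCTGTTTTTATGTATG
TTTGTCAACGTGAAACTCGTGAATCTTGGAATGAATGTGAAGTTTCTGAATCCGTATATTGTAGACATTT
TTAGCGTGCTTAATAACGAGGTGTGATGGTGGAATGCTTGCACGGACATGTTACCGAGATCAGAATGTTG
CATTGCCAGGGTTGAGAGGTTAAACGGCAAGGAAACGATTTGGTAATGCTCTGTCTGAAGATCGTCATTC
TAAATCTGCTCCTGCTAAATCTGCTAAACGTAAAGATATGCTGATTCAATGGTTTACTTCTTCTGCTTTT
AATCAAAAATGGCATGCTTATATTGATTGGGATGAATCTCGTGAAGATGCTCCGTGCGTGTCGATGTATC
TACACTACGTCCCTCTTATACTGAGTATGGTAGGCATCAGGTTCCATGCAAGAACCTCCTCCGGACCATT
TTTGGATGCGTGCTTGGTGTCATGAATTTGATCTGATTAATATTCAACATTCTCTGATGCTGAATGATGA
ATTTATTTTTATTAAAATGAAAGAACAATGTGAAGAAATTGTTAAAGGAGTGCGCCTATAAGATATATAT
AGACGATGGTCATCTCGGCCGAAAATACAGATAGTATGGGCTCGTCCTTCTAATCGTTCTAAAGCTCCTT
TTTGTTGTTGGCGTAATTCGGAGTGTCATGTACCCTGTGCTTGAACGGCGGGGACTACGTAGTGCCCTAA
CGTAGAACCGGTCGTAGCAGTCAGGTGGTGTTGTGATCCTCAATCTAAACTGTCTCAACTGATTAATCAT
TTTTCTGCTAAACGTAATTGGAAAGTTGTTCTGGTTTCTCGTCCTGCTACTGGTTCTTGTAAATTTGTTC
TGCAAGCTGCTCATAATGTTAATTCTCTGTATCGTTGGCATTATTGGGATGCCAACCCACAGCCGCTTTC
AGTTAAGGGAAACATGTGGCAGTCCCGGCATCTGACTTGCTTAAGACAGGCCGGTAATCTTCGGACGTGT
AGGGGTCGCGATCAACGCAGTACGCAGATACTTCGGAATCCTGAAGAAGTTGCTCCTCTGTTTCGTGATC
ATCTGCCTTATCATATTGGTTATGGTATTGCTTCTTATATGCCTATGTTTTTTCCTTCTAATGCTGTTGG
TGATCATCGTTTTATGGATGATTGGGCTCGTAAACCTTTTACAATATACGAGATGGGAGTCGGCCGGCCA
TCTGGCATTGTCCGCATACTTGGTTCTGAATCACAGCCTAGCAAAAATGGGGTCTTGCAGAAAAGCACTT
TGGTTCTTGTCATGGTTTTGGTACTTTTGGTCGTAATTCTTTTCCTTATTCTACTTGGGAATCTAATGAA
ACTATTTGTCGTGATGCTGTTAATTGGATGGCTTATCAAAATGAACCTCATACTCCTTATCAAAAAATTT
GGGCTGAACATGCTGTTAAAAATCTTTGCTCTGAAATCCGCCCCGGCAGACATCACCGCTGCACTCACAC
CACTCCTTCAAGGAGGGATTCGCCGCCAGCGTAAGCCGAAGAACTGTCTTCGTGCCGCCTAAACATTTAT
ATCCACCTCATCAACCTCGACTCCCTACTTGGCGTGTTCGTAAAATGGGTAAAGTTAAAGGTCCTTGTCG
TGAATCTTGGCAAAAATTTGGTACTACTTATTGGTATGATTATTGGCCTGAAGCTATTGAAAAAGGTATG
CGTCGTATTCGTTCTTCTCTTAAGCCCAACGTCCGAGCTCCATGGTGTTCGTTAAATTAAGGGATCCCTT
TAGATCATGCCATCGTGTTCACTCAACTGCTCTGTGGATACCTCGAGCCTGTGCGCTGACACGTAAACCC
CAGAGGTCTCGAGGGCCTTCACGCTAATAAAGATTTTGCTGAATTTTTTAAAATGTGTGGTTATATGCGT
AAAGATGCTCGTAATTGGTTTTGGACTGTTAAAGCTCCTTTTATTTTTAAACGTTCTGTTGGTGATTTTC
GTGTTCGTTTTGGTATTCATATTCAAATGCCTAATGCTTGGTGGAAAATGTGGCGTCGTGTTATGTGGAT
TTTTTGGAAATAATGAAACAAGAGTTATTTCCCGAGTCACAAGCCCCACAAAGGGCCATGCAATCTACAA
AGGGAGCCTATTACCGAAAATATGTGTTTTAATTATTCTGCTG
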