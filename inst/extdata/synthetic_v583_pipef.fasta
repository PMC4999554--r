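>synthetic_V583_PIP_EF synthetic stand-in for EF0858 (2667 nt ORF, VR nt 1024-1482)
ATGGTGGCTTTGACTATATACCGAACACATACCGGAATCAAACCACCCTACGCCTTTGAT
CGTCCTTTTAGAGCCCGAAATTGGAGTTACCAATTCTTATTCACGCGCAGGTCTACATAC
GCGCTCAGGCGTAACTCTAGCAAGTTCGCGTGCATCCAGGTAATATGTTACTCCTGTCCG
CCGCCCGCTACCCATAAAACTGACGTGCAGTTAGATACCGACGCTCTTCGAATTTACGAG
ACTCGCGAGGTCATGGCTATTATGATAATGCATTTAAAGGAGCGTAGCGAGCCCGGCTTT
TTCTTAAACGAAGTTATTAGCTCGCGATTAGTACACGGTAACCCGGAGGTGCTACGGACG
TCCAGGAGAATTCTGCTACAAGCTAGATGCATAATAAAAAGCCATGTCGCTGGGTTCGAA
ACTGAAGGAAAACTACAGCCGGCACGGGAACCACGCATGGTGACAGTTTTATCATCTCTC
CTAGGTCTCTTCATAGTTGGGTGCCTCGGGACGACAGCATGCTCCTCGGCCAGTGTCGAC
GCCCACTTGGCTCGGACAGCTTCCTCTCTCCGTATATCAGCCGGCCAAAAACTGCAATGT
TATATTATCCCGCTCCGTTATTCTATAACTCCAGGGTCACGACGAATGGAGATGGCGAAT
CAACAGATATCCTCTTTCTCATACAGTCCAATCCGCAACGGTCAAAACCCTGTTCGTATT
CCCCTAAGATATGTTGTACTGGATGGTAATGCTGACGGGCTACGACCAGTGCACAACAAG
GATAGTGTAAGCATATCGTATAATGAGGTGTCAGTGGCCTACATAGGACTTTCCCGTCAG
GGTGTACTTCATCGGTCTCCCCGTTATCCTCGTCGTGGTCCGTCTCGCGCAAGCTTAGTG
GTGAACGCCCGCCGTGGATTACAACTGGTGTGTATCCCTTGGATTGGTCACATCCCTCTT
GGAGTCAATTGGCTTCTGTTACTAGAGAATTTATTTTATTGGAGGAACAAGCGTAACCCT
GCCGGGGAAATCCAGACGTTGTCCGTGAGGTGTCTTACGTTCGCCCTTTATTTAGACGCT
CGTAGAGCAGGTCACGCGGGGCATGTGGTGTCAATAAATCAGAGTGACTCAGCTACTACG
TACCATACACGAATGTTCGTGTCCCACGGCTCACGCCCGCGGAGATCCTTAGACTCCGTT
GCCTATAGTATGCTCTCCCGGGTTGACAAGCGTGACAGTACGCAGGACCACGCCACTCAC
AACTTTGTGCGTAATTTTCCTTCACCCCCCGCTACCACGGGGCACAGGGAAGCCGAAGCC
TCAAGCATTGCTCCGTACTGTAGGTCCGTCGGGGGGGTCCATGAGCGGCCATTAGATCAG
CGACCGAACTTGGTGAGCACTGCGGAAACGCAATACTTTTATATACATCAAGCTAATCAA
GTGATATTGTTTCCGGCTCACTCACGGGTGCTTGCGCAAGCTCTAATCTTTCAGAGGGTA
ATATACCAATATCAAGGACTTAAGTCCCTAAGGAGAGGAGCGCTTATAGGTAAACGACGA
TATAAGATCTTACTAGCGCTGGTGACTCTTATGGAAATCACAGGGGTGAGAGAGAACTCC
ATCTACCGTCGTTTGCAACAACATGAATTGGCAGTGGCCATCCGTTCGACTGAGAGCATA
TCCCTCACGATAGTGATCCCACCGCCCTTTCCCAATGGAGAGGAAGCCTTAGTGCGCGTG
ACGATCGTCAATACGCATTCTCGTAGCATACTTCCGGCGAAGCACCATCACGAGCGTATT
TGTATGAATCCCGGAGTCAACCAGAAACTAGGGATCGTTTATCCACTTGTCTACCGTAAC
ATCGAACTTGGTCTCCCGCGACATCATATGTTCCTCTGTCAAGCCGATAATTGTTTAAGA
AATCTGTGTGATCCAATCCAGCCGAACGCCGGCGTACCCAAACTCAATGTCCATTATTTC
GACGACGCACTATCTTCAAGGAGCGACGCCCAAAGGAATCACGGGGGTCTAAAAATTGCG
ACGCTTATCTTGATGTACTCACAGATGGCATGCTGTCCAGCAAAACCTTGGCACACCGTA
GAGTCGCTCACGCTAACAAGGTTTACGTCCTCTGCGAGCGGGTACCTGGACGTGGCGTTA
GGCCGGGTTGTATTAATCGTATTATACGACATGACGACGGCGGAGGTCGCAGGCAGAAGT
AAACACCAGGTCTACGTCCGTGTCGTCGTCGTTTCCGCCTACAATAGGGGACGATGTGAA
AACCATGACAACCTTGTTCCCGATCATTCTAGTCTCCCGCTGAGCACAGGGCCGCATCGT
GAACGTGGACGTCCCGTAACAGTAGTATTCGCTACACAGAGAGGCTCCTTGCCTCAAATC
TTGCTACCCATCGACACTCGCAATTTACGCGTGGTATTGCTCTTCAGCTTCACACTTATA
TTATTACTGCCATTAATTCCCTCGATTACTCTTCAGATTAAGTTGTCTCCAACTCAAATT
CCAGGCGTCCCTCTGGTCCCGCGTCTGTCTCCTGGAAACCCCATGCGGCGGCATGTTGGG
ATCGTGAAAGAACGGAATTTTGTCCACGACGTACGCATTAATCCAAAGCTTATGCGAGAC
GCAGAGACTAGTGTCCGACCTGGGTAA
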