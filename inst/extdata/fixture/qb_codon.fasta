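>qb_g1
CGTTTTGGTCGAGCTTCACAGTACGGCCACGCTAGCGTTGGCTATCTAGCGGCCGGGGCAGCGGGCTATCGTCCTGTGCGGCGAGTAAGCACCGATGAGGGCTTTACAGTAAGCATTGATTGCTCTTACCCGGAACGTCGCACCCTGACCATAATGAGCGTCTTTAGAGGACGTATATGGGAGGGTTGGAGGGATCATCCCCATTGGTACGCAACAAAGCATCCGATTCCGCTTTCCTCGCGTTTTACGCTCGTCAGACGGAACCGTGACCTTAGCTTTAGTCTATGCCGGCTTCCGGTTCTGAGTCCGCTCGTTGTCCCTCATACTTGCGGGGCATTAGTTTACACTGTTCATAATCCAACGCCGCGGCCTAGGCATATACTCGCATGTTTTCTTGGCAGTCTACCTGTTCCCTCTGGATATCGTCCGGTGCCATTCACATGGACCCCCCATTCAACCAAAGGCTGCAATCGCCTGCAAGTGGAGGACCCAAGACATGAATGTCTAACCCACTCTTCCGGAGGACGTCTCGCACTAGCGCCGGCATTCATTCTCTACCACTCGGTTACGACCGATTCTATTGCCAAATGGCCTGTTCTGCTGCAATCGGTGCACGATCACGCCATCGGGATTGCACCGCTGAGTATGAGACTCCGGAACAGTCCCGGGTATTTGTCCACAATACATCGCGCCTGGCCGCGCCAACTGGTCGAAAAACGGCGATGCCTCAACTCCTCCGCCAGCCTTTGGACTTTCTACGGCTCGCGTGGTTCGAACCGTCTTCTGAATTCGTTACGCCGTAGCAAAGGAGGTATATCCTACCAGAGTTCCTGTTCCTGCTTTCTTATGGACCAAGCCTGCCAGATGCGAGGTAAGAAGACTCGGATCAATTGGTCAGCC
>qb_g2
CGTTTCGCTCGAGCCTCGCAATATGGCCACGATAGCGTGGGCTTTCTAGCAGCCGGGGCAGCAGGCTATCGCCCCGTACGGCGAGTAAGCACCGATGAAGCATTGACAGTTAGCAGCGATTCATGTTACCCAGAACGACGAACGCTGACCATAATGGGTGGCCTTCGGGGACGTATATGGGAAAGTTGGAGTGATCCTCCCAACTGGTATGCGACCCAGCATCCGATTCCGCTTTCTTCGCGTTTTACGCTCGTTAGACGAATTCGTGACCTTAGTTTTAACTTGTGCCGACTTCCGGTCCCGAGCCCCCTCGTTATTCCTCATACTTGCGGGGCGTTAGTGTATACTGTTCATATTCCAACGCCCCGGCCTAGACACATCCTCGCCTGTTTTCTGGTGTTTTTACCGGTTCCCTCCAGATATCGTCCGGTACCATTTACCTGGTCTCCTCACTCGACCAAAGGCCGCGATCGTCTGCAACTGGAAGACCCCCGACATGAGTGTCTAACCCACTCCCCGGGACGGCGTCTCCTACTAGCTCCGGCATTCATTCTCTATCACTCAGGTTCACCACATCCTATCGCCAAATGGCCCGTTCTGCTGCAGTCAGTGCACGATCATGCTATCGGGATTGCTCCTCTAAGTATAAGACTCCGTAATAACCCGGGGAATTTATCAACTATACATCGCGCATGGCCGCGCCAGTTAGTCGGAAAACGCCGTTACCTTAACTCGTCTGCCAGTCTTTGGACTTTCTACGGTTCACGAAGGTCTAACAATCTTCTCAACACCTTACGGCGTCGCAAAGGAGGTATATCTTCCCAGGGCTCGTGTTCCTGCTTTCTCATGGACCAAGCTTGCCAGATGCGGGGTAAGAAGGCTTGGATCAATTGGTCCGCT
>qb_g3
CGGTTCGCTCGAGCCTCGCAATATGGCCACGATAGCGTTGGGTATCTTGCGGCCAGGGCAGCAGGCTATTGTCCCGTACGGCGAGAAAGCACCGATGAAAGGTTTACAGTTAGCAGTGATTCATCTTACCCGGATCGTCGATCGCTGACCATAATGAGTGTGTTTCGGGGACGTATATGGGATGGTTGGAGTGATCATCCCAATTGGTATGCGACCCAGCATCAGATCCCGCTTTCTTCACGTTTTACGCTCGTTAGGCGAAATCGTGACCTCAGCTTTAACCTATGCCGACTTCCGGTCCTCAGTCCTCTCGTTATCCCTCATCCTCGCGGGGCGTCAGTGTATACTATTCATATTCCAACACCGCGGCCTAGACATATACTCACATGTTTTCCTGGGTATTTACCCTTTCATTCCAGGTATCGTCCGGGACCATTCACATGGTCTCCTCACTCCACCAAAGGCTGCGATCACCTGCAACTCGAAGACCCACGACATGAGTGTCTTACACACTCCCCGGGACGGCGTCTCCTACTAGCGCCTGCATTTATTCTCTACCACTCAGTTTCATCGGACTCAATCACCAAGTGGCCGGTTCTGCTGCAATCAGTGCACAATCATGCTACCGGCATTGCGCCTCCGAGTATAAGACTTCGAAATAATCCCTGCAATTTATCCACTATACATCGCGCATGGCCGCGTCAATTAGTCGGTAAACGCCGCTGCCTAAACTCGTCTGCCAGTCTTTGGACTTTCTACGGTTCACGGGGTTCTAACTATCCTCTGAACTCTTTATCGCGTCGCAAAGGAGGTATCTCATACCAGGGTTCGTGTTCTTGTGTTCTCATGGACCGGGCCTGCCAGATGCGGGGTAAGAAGACCCGGATCAATTGGTCAGCT
>qb_g7
CGTTTCGCTCGAGCCTCGCAATATGGCCATGATAGCGTTGGGAATCTTGCGGCCAGGGCGGCGGGCTTTCGTCTCGTACGGCGAGAAAGCACCGATGAAGGGTTTACAGTTAGCAGCGATTCATCTTACCCTGAACGCCGAACGCTGACCATAATGAGTGTCTTTCGGGGACGTGTATGGGATGGTTGGCGTGATCATCCCAATTGGTATGCGACCCAGCATCCGATTCCGCGTTCTTCGCGTTTTACGCTCGTTAGGCGAAATCGTGACCTTAGCTTTAACCTATGCCGGCTCCCGGTCCTCAGTCCTCTCGTTATCCCTCATACTCGCGGGGCGTTAGTGTATAATATTCACATTCCAACGCCACGTCCTGGACATATACTCGCATGTTTTCTTGGGATTTTACCCGTTCTCTCCAGATATCGTCCGGTACCATTCACATGGTCTCCTCGCTCGACCAAAGGCTGCGATCGCCTGCAACTGGAAGACCCACGGCACAAGTGTCCAACACATTCCCCGGGACGACGTCTTCTACTAGCGCCCGCATTCATTTTCAACCACTCGGTCTTATCCGACTCAATCACCAAATGGCCGATCCTGTTGCAATCAGTGCACTATCATGCTATCGGGATTGCTCCTCTGAGCAGAAGAGTTCGCAACAATCACGGGAATTTATCTACTATACATCGCGCATGGCTACGTCAATTAGTCGGAAAATGCCGCTGTCTTAACTCGTCTGCCAGTCTTTGGACTTTCTACGGTTCTTGGGGGTCTAACTATCCTCGGAACTCGTTACGGCGTCGCAAAGGAGGTATCTCATGCCAGTGTTCATGTTCCTTCTTCCTCATGGACCAAGCCTGCCAGATGCGGGGTAAGAAGACTCCGATCAATTGGTCGGCT
>qb_g8
CGTTTCGCTCGAGCCTCGCAATATGGCCACGATAGCGTTGGGTATCTTGCGGCCAGGGCGGCGGGCTTTCGTCTCGTACGGCGGGAAAGCACCGATGAAGGGTTTACAGTTAGCAGCGATTCATCTTACCCTGAACGCCGTACGCTGACCATAATGAGTGTCTTTCGGGGACGTGTATGGGATGGTTGGCGTGATCATCCCAATTGGTATGCGACCCAGCATCCGATTCCGCGTTCTTCGCGTTTTACGCTCGTTAGGCGAAATCGTGACCTTAGCTTTAACCTATGCCGACTCCCGGTCCTCAGTCCTCTCGTTATCCCTCATACTCGCGGGGCGTTAGTGTATAATATTCACATTCCAACGCCACGTCCTGGACATATACTCGCATGTTTTCTTGGGATTTTACCCGTTCTCTCCAGATATCGTCCGGTACCATTCACATGGTCTCCTCGCTCGACCAAAGGCTGCGATCGCCTGCAACTCGAAGACCCACGACACAAGTGTCCAACACACTCCCCGGGACGACGTCTCCTACTAGCGCCCGCATTCATTTTCAACCACTCGGTCTTATCCGACTCAATAACCAAATGGCCGATCCTGTTGCAATCAGTGCACAATCATGCTATCGGGATTGCTCCTCTGAGCAGAAGAGTTCGCAACAATCACGGGAATTTATCTACTATACATCGCGCATGGCTACGTCAATTAGTCGGAAAACGCCGCTGTCTTAACTCGTCTGCCAGTCTTTGGACTTTCTACGGTTCTTGGGGGTCTAATTATCCTCGGAACTCGTTACGGCGTCGCAAAGGAGGTATCTCATGCCAGTGTTCATGTTCCTTCTTCCTCATGGACCAAGCCTGCCAGATGCGGGGTAAGAAGACTCCGATCAATTGGTCGGCT
>qb_g4
TGTTTTGCTCGAGCCTCGCAATATGGCCACGATAGCGTTGGGTACCTAGCGGCCAGGGCAACGGGCTATCGTCCCGTTAGACGAGAAAGCACCGATGAAGGGTTTACAGTTAGTAGCGATTATTCTTACCCCGAACGCCGAACTTTGACCATAGTGAGTGTCTTTCGGGGACGCATATGGGAAGGGTGGAGTGATCATCCCAATTGGTATGCGACCCAGCATCCGATCCCGCTTTCTTGGCGCTATACGCTCGTTAGGCGTAATCGTGACCTAAGCTTTAACCTATGCCGACTTCCGGTCCCGAGTCCTCTGGTTATCCCTCATCCTCGCGGGGCATTAGTATACACTATTCATATTCCAACGCCTCGTCCTAGACATACACTCGCATGCTTTCTTGGGATTATACCTGTTCCCTCCAGGTATCGCCCGGTACCTTTCGCATGGTCTCTTCACTCGACCAAAGGCTGCGATAGCCTGCAACTAGAAGACCCACGACATGAATGTCTTACCCACTCCCCGGGGCGATGTCTACTTCTAGCGCCGGCATTCATCCTATACCACTCGGTTTCACCCAATTCAATCATCAAGTGGCCTGTTCTGCTGCAATCCGTGGACGATCATGCTATCGGTATTGCTCCCCTGAGCATAAGACTTCGCAACGATCCCGGAAAATTATCCACGATACATCGCGCATGGCCGTGCCAATTAGTCGGAAAACCCCGCTGCCTTAACTCGTCTGCCAGTATTTGGACTTTCTACGGTTCACGGGGGTCTAACAATCCTCTAAACTCGTTACGGCGTCGTAAAGGAGGCATATCTTGCCAGGGTTCGTGTTCCTGCTTTCTAATGGACCAAGCCCGCCAGATGCGGGGTAAGAAGACACGGATTAATTGGTCAGCT
>qb_g5
TGTTTTGCTCGAGCCTCGCAATATGGCCACGATAGCGTTGGGTACCTGGCGGCCAGGGCAACGGGCTATCGTCCCGTCCGGCGAGAAAGCACCGATGAAGGGTTTACAGTTAGCAGCGATTCATCTTACCCCGAGCGCCGAACTTTGACCATAATAAGTGTCTTTCGGGGACGCATATGGGAAGGATGGAGTGATCATCCCAATTGGTATGCGACCCAGCAACCGATTCCGCTTTCTTCGTGCTTTACGCTCGTTAGGCGAAATCGTGACTTGAGCTCGAACCTATGCCGACTTCCGGTCCCGAGTCCTCTGGTTATCCCCCATCCTCGCGGGGCGTTAGTATACACTAGTCATATTCCGACGCCGCGGCCTAGACATATACTCGCATGTTTTCTTGGAATTATACCTGTACCGTCCAGATATCGTCCGGTACCGTTCACATGGTCGCCTCACTCGACCAAAGGCTGCGATCGCCTGCAACTCGAAGACCCACGTCATGAATGTCTTACCCACTCCCCGGGGCGGCGTCTTCTATTAGCGCCGGCATTCATTCTATACCACTCGGTCTCACCCGATTCAATTACCAAATGGCCTGTGCTGTTGCAATCCGTCGACGATCATGCTATCGGGATTGCTCCCCTGAGCATAAGACTTCGCAAGGATCCCGGGAGATTATCCACTATACATCGCGCGTGGCCGCGCCAGTTAGGCGGAAAACCCCGCTGCCTTAACTCGTCTGCTAGTCTTTGGACTTTCTACGGTTCACGGGGGTCCAACAATCCTCTAAATTCGTTACGGCGTCGTAAAGGAGGCATATCTTGCCAGGGTTCGTGTTCCTGCTTTCTAATGGACCAAGCCTGCCAAATGCGGGGTAAGAAGACTCGGATTAATTGGTCAGCT
>qb_g6
TGTTTTGCTCGAGCCTCGCAATATGGCCACGATAGCGTTGGGTACCTAGCGGCCAGGGCGACGAGCTATCGTCCCGTTCGGCGAGAAAGCACCGATGAAGGGTTTACAGTTAGCAGCGATTCATCTTACCCCGACCGCCGAACTTTGACCATAATGAGTGTCTTCCGGGGACGCATATGGGAAGGATGGAGTGATCATCCCAATTGGTATGCGACCCAGCATCCGATTCCACTTTCTTCCTGCTTTACGCTCGTTAGGCGAAATCGTGACTTGAGCTCTAACCTATGCCGACCTCCGGTCCCGTGTCCTCTGGTTATCCCCCATCCTCGCGGGGCGTTAGTATACACTAGTCATACTCCAACGCCGCGGCCTAGACATATACTCGCATGTTTTCTTGGAATTATACCTGTTCCGTCCAGATATCGCCCGGTACCGTTCACATGGTCGCCTCACTCCACCAAAGGCTGCGATCGCCTGCAACTCGAAGACCCACGACACGAATGTCTTACCCACTCCCCGGGGCGGCGTCTACTATTCGCCCCGGCATTCATTCTATACCACTCGGTTTCACCCGATTCAATTACCAAATGGCCTGTGCTGTTGCAGTCCGTGGAAGATCATGCTATCGGGATTGCTCCCCTGAGCATAAGACTCCGCAACGATCCCGGGAAATTATCCACCATACATCGCGCGTGGCTGCGCCAGTTAGTCGGAAAACCCCGCTGCCTTAACTCGTCTGCTATTCTTTGGACTGTCTACGGTTCACGGGGATCCAACAATCCTCTAAATTCGTTACGGCGTCGTAAAGGAGGCATATCTTGCCAGGGTTCGTGTTCCTGCTTTCTAATGGACCAAGCCTGCCAAATGCGGGGTAAGAAGACTCGGATTAATTGGTCAACT
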