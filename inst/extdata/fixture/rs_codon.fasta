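>rs_g1
GTCGCAACTGAGCCCCCAGCCAATACTTGTATCCGGGAAAACGCCGAGGAGGGCGATCCCATCATTGTCCGGGCCCAAACATCCGAGCCTCCTCACATGGCCCAAATCAAGAATGCATTACTGCGTCCCGAGGTATGGTCCGACGAACGATACCTTAAGTTGGACAAGCGAAATACGATGAAATGCAATTTGTTTCGGCCAGGACGATGCACACCCCGGTGCCTGCGTCGCTCCCTACTTATTGGTGGTCCGCAGATTGGTATCAGGATGTTCGTAACACGTCCGTCGTATGCTGTGGATGAGGAATTTAACTCCCTGCGAACGGGCGCCTCAATGCCAACACGTACCCGCGTAAGGTACAGACGGCTGCGTCTAAGGTTTAATCGCTATCCCCTCTATTTGGATTGGCATCCAGACCGGATCTTGGCTCCCGAGCAGGCCAAAGTGAGAAAGAACTCGACCGCTCCGGGGCACAGGGGAAGACTTAATACTCCAACTACCCAGTATCACGCACAACACTATGAATGTTGCTCCGCAAACCCGTTCGATATCGAATTTACAGGGACCCGGAGAGTTGTTAAATGCGGCCATTCTTACAAGATCTTCGTATCTACCATGGGAGACCATCCGGGGCAATGTAGCGCCAGAGAAATTGCGTCGGGCAGTTGCTCCGATGTAAGGCCGACGTCCATGCATGTCCAGACGCTGTGGTTGCCACGAATAAGTGGAGTTCTCGTCGGAATCTTGGTAATCCACACGAAGCGCTTCCACGTCCCACCTGGGGCCGGTCTCTATGGTTCAAGATCCCAACAAGATCTGGCAGGACGTAGACACGGCCGCATGCGACAGCGTGATTCGAATCTGCCTGGCCTTATGAAAGATGTTGAATCAGCCGGAGAG
>rs_g5
GTCGCGCCTGGACCCGCCGCACATACTTGTGTCCGGGAAAACGCTGAAAACAGAGGTCCCATCATTGTCTGGGCTCAGACTTCCGAACCTCCACAGATGGCGCAAATCAATAATGCATTACTGCGTCCCGATGTGTGGTCCGACGAACGATACCCTAAGTTAAACAGACGTAACACAATTAAATGCAATTTGTTACGAACAGGACGATACACACCCCGCAGCCTGCGCCGTTCCCTCCTTTTTGGTGGTTCGCAGATCGGTATCAGAATGTTTGAAACTCATCCATCCTATGCCGTTGATGAGCAATTTAACTCCCCCCGAACAGGCGCCTCGATCCCAACTTGTACTCGCGTAAAACACAGACGGCTGAGTCCAGGATTTAATCGCTATCCCCTCTATTTGGATTGGCATCCAGACCGGATCTTGGGTCCCAAGCAGTCCAAGGTTAGAAAGAACTCGACCTCTCCAGGTCACAGGGAAAGACTTGACACTCCAATTACCCAGCATCACGCGCAATACTATGAATGTAGCTCCGCAAACCCGTTCGATATCGAATTTACAAGGACCCGGAGACTTGTTAACTCCGGTCATTCTTACGAGATCTTCGGATCAACCATGGGAGCCCATCCGGGGCAATGCAGCGCGAGGGAAATTGTGTCCGGTAGTTGCTCCGATGGCAGCCCTATTTCCATGCGTGTCCAGACGCTGTGGTTGCCACGAATAAGTGGAGTTCTCGTCGGCATCTTAGTGATCGACACGAAACGCCTTCACGTCCCCCCTGGGGCGGGTATGTATGGTTCTAGGCCCCAACAGGATCTGGCAGGACGTGGCCATGGCAGCATGCGACAGCGTGATGCGAATTTTGCTGGATTTATGAAGAATGTTGAATCAGACGGAGAG
>rs_g6
GTCGCGCCTGAACCCGCCGCCCATACTTGTATCCGGGAAAACGCTGAGGACAGAGGTCCCATCATTGTCTGGGCTCAGACTTCCGAACCTCCACAGATGGCGCAAATCAACAATGCATTACTGCGTCCCGATGTGTGGTCCGACGAACGATACCTTAAGTTAAACAGACGTAACACAATTAAATGCAATTTGTTTCGAACAGGACGATACACACCCCGCAGCCTGCGCCGCTCCCTCCTTTTTGGTGGTTCGCAGATCGGTATCAGAATGTTTGAAACTCATCCATCCTATGCCGTTGATGAGCAATTTAACTCCCCCCGAACAGGCGCCTCGATACCAACTGGTACCCGCGTAAAACACAGACGGCTGAGTCCAGGATTTAATCGCTATCCCCTCTATTTGGATTGGCATCCAGACCGGATCTTGGGTCCCGAGCAGTCCAAGGTTAGAAAGAACTCGACCGCTCCAGGTCACAGGGAAAGACTTGACACTCCAATTACCCAGCATCACGCGCAACACTATGAATGTAGCTCCGCAAACCCGTTCGATATCGAATTTACAAGGACCCGGAGACTTGTTAAGTCCGGTCATTCTTACGAGATCTTCGGATCAACCATGGGAGCCCATCCGGGGCAATGCAGCGCGAGGGAAATTGTGTCCGGTAGTTGCTCCGATGGCAGCCCTATTTCCATGCGTGTCCAGACGCTGTGGTTGCCACGAATAAGTGGAGTTCTCGTCGGCATCTTAGTGATCGACACGAAACGCTTTCACGTCCGCCCTGGGGCGGGTATGTATGGTTCTAGGTCCCAACAGGATCTCGCAGGACGTGGCCATGGCCGCATGCGACAGCGTGATGCGAATTTTGCTGTACTTATGAAGAATGTTGAATCAGCCGGAGAG
>rs_g4
GTCGCGCCTGAACCCGCCGCCCATACTTGTATCCGGGAAAACGCTGAGGACAGAGGTCCCATCATTGTTTGGGCTCAGACTTCCGAACCTCCACAGATGGCGAAAATCAATAATGCACTACTGCGCCCCGAGGTGTGGTCCGACGAACGATACCTTAAGTTAAACAGACGTAACACAATTAAATGCAATTTGTTTCGAACAGGACGATACACACCCCGCAGCCTGCGCCGTTCCCTCCTTTTTGGTGGTTCGCAGATCGGTATCAGAATGTTTGAAACTCATCCATCCTATGCCGTTGATGAGCAATTTAACTCCCCCCGAACAGGCGCCTCGATCCCAACTGGTACCCGCGTAAAACACAGACGGCTGAGTCCAGGATTTAATCGCTATCCCCTCTATTTGGATTGGCATCCAGACCGGATCTTGGGTCCCGAGCAGTCCAAGGTTAGAAAGAACTCGACCGCTCCAGGTCACAGGGAAAGACTAGACACTCCAATTACCCTGCATCACGCGCAACACTATGCATGTAGCTCCGCAAACCCGTTCGATATCGAATTTACAAGGACCCGGAGAGTTGTTAAATCCGGTCATTCTTACGAGATCTTCGGATCAACCATGGGAGCCCATCCGGGGCAATGCAGCGCGAGGGAAATTGTGTCCGGGAGTTGCTCCGATGGCAGCCCTATTTCCAGGCGTGTCCAGACGCTGTGGTTGCCACGAATAAGTGGAGTTCTCGTCGGCATCTTAGTGATCGACACGAAACGCTTTCACGTCCCTCCTGGGGCGGGTATGTATGGGTCTAGGTCCCAACAGGATCTGGCAGGACGTGGCCATGGCCGCATGCGACAGCGTGATGCGAATTTTGCTGGACTTATGAAGAATGTTGAATCAGCCGGAGAG
>rs_g3
GTCGCGCCTGAACCCGCCGCCCATACTTGTATCCGGGAAAACGCCGAGGTCAGAGGTCCCATCATTGTCTGGGCTCAGACTTCCGAACCTCCCCAGATGGGGCAAATCAATAATGCATTACTGCGTCCCGATGTGTGGTCCGACGAACGATACCTTAAGCTGAACAAACGTAACACAATTAAATGCAATTTGTTTCGAACAGGACGATACACACCCCGCAGCCTGCGCCGTTCCCTCCTTTTTGGTGGTTCGCAGATCGGCATCAGAATGTTTGTGACTCATCCATCCTATACCGTTGACGAGCAATTTAACTCCCTCCGAACAGGCGCCTCGATCCCAACTGGTACCCGCGTAAAACACAGACGGCTGAGTCCAGGATTTAATCGCCACCCCCTCTATTTGTATTGGCATCCAGACCGGATCTTGGGTCCCGAGCAGTCCAAGGTTAGAAAGAACTCGACCGCTCCAGGTCACAGGGAAAGACTTGACACTCCAATTACCCAGCATCACGCGCAACATTATGAATGTAGCTCCGCAAACCCGTTCGATATCGAATTCACAAGGACCCGGAGAGTTGTTAAATCCGGCCATTCTTACGAGATCTTCGAATCAACCATGGTTGCCCATCCGGGGCAATGTAGCGCGAGGGAAATTGTCTCGGGTAGTTGCTCCGATGGCAGCCCTATTTCCATGCGTGTCCAGACGCTGTGGTTGCGACGAATAAGTGGAGTTCTCGTCGGCATTTTAGTGCTCGACACGAAACGCTTTCACGTCCCCCCTGGGGCGGGTATGTATGGTTCTAGGTCCCAACAGGATCTGGCAGGACGTGGACATGGCCGCATGCGACAGCGTGATGCGAATTTTGCTGGACTTATGAAGAATGTTGAATCAGCCGGACAG
>rs_g7
ATAGCAACTAACCCCGCCACCAATACTTGTATAAGAGAAAACGCTGAGGAGGGACGTTCCATTATCTTTTGGGCACAAAGATCCGAAACTCTACACATGGCGGCAATCAAAGACGGGTTACTGCGTCGTGAAGTATGGTACGACGAACAATGCCTTAAACAAGACAAGCGTTATGCTATGAGATGCAATATGTTCCGGACGGGACGATTCGCACGCCGCATTATGCGCCGCTCAACGCTTCTTGGGGGTTCACAAATTGGTAGTAGGATGTTCCTTAAACTTTCATCGTATGCCGTTGATAAGCAAATTAAGTCCCAACGTATGGGCGCTCCGACGCCAACCGGTACCCGAGTACGGAACGATCGGCTGAGTCTAGGATTGAACCGCTACCCCCTCTATTTCGATTCCCATCCAGACCGGTTCTTGGCTCCAGGTCAGGCTCAGTTTAGAAAGAAAGCGGCCGCTCAAGGACACAGGGAAAGAATCGTCACTCCAACTGCCCAGCATCACGTACAACATTATAAGGGCTGCTCGGTAAACCCGTCCGAAATCGAATTCACAGTGACTAGGAGAGCTGTTAAATGCGGGCATGCTCGGAAGATCTTCGAATGGACCATGGGTGCCCGCCCCGGGCAATGTAGTGCGAGGAAAATCGCGGAGGTTAGTTGCTCCGTTGCAGGGCCGACCTCCATGCATGCACAGACGCCGTGGTTGCGACGAATCAATGGAGTTCTGGTCGGAATCTTGGAGATGGACACGAAGCGTTTCCACGTACCCCCTGGGCCCGGTCCGTACGGTTCGAGGTCCCAACAAGATCTGGCTGGTCGTGAACATTGTCGCATGCGGCAGCGTGAATCGAATCTTCCTGGACTTACGAAAGATGTTGAATCTGCCGAAGGG
>rs_g8
ATAGCAACTAACCCCGCCACCAATACTTGTATAAGAGAAAATGCTGAGGAGGGACGTTCCATTATCTTTTGGGCACAAAGATCCGAAACTCCACACATGGCGGCAATCAAAGACGGGTTACTGCGTCGTGAAGTATGGTACGACGAACAATGCCTTAAACAAGACAAGCGTTATGCTATGAGATGCAATATGTTCCGGACGGGACGATTCGCACGCCGCATTATGCGCCGCTCAACGCTTCTTGGGGGTTCACAAATTGGTAGTAGGATGTTCCTTAAACTTTCATCGTATGCCGTTGATAAGCAAATTAAGTCCCAACGTATGGGCGCTCCGACGCCAACCGGTACCCGAGTACGGAACGATCGGCTGAGTCTAGGATTGAACCGCTACCCCCTCTATTTCGATTCCCATCCAGACCGGTTCTTGGCTCCAGGTCAGGCTCAGTTTAGAAAGAAAGCGGCCGCTCAAGGACACAGGGAAAGAATCGTCACTCCAACTGCCCAGCATCACGTACAACATTATAAGGGCTGCTCGGTAAACCCGTCCGAAATCGAATTCACAGTGACTAGGAGAGCTGTTAAATGCGGGCATGCTCGGAAGATCTTCGAATGGACCATGGGTGCCCGCCCCAGGCAATGTAGTGCGAGGAAAATTGCTGAGGTTAGTTGCTCCGTTGCAGGGCCGACCTCCATGCATGCACAGACGCCGTGGTTGCGACGAATCAATGGAGTTCTCGTCGGAATCTTGGAGATGGACACGAAGCGTTTCCACGTACCCCCTGGGCCCGGTCCGTACGGTTCGAGGTCCCAACAAGATCTGGCTGGTCGTGAACATTGTCGCATGCGGCAGCGTGAATCGAATCTTCCTGGACTTACGAAAGATGTTGAATCTGCCGAAGGG
>rs_g2
GTAGCAACTAACCCCGCTGCCAATACTTGTATAAGAAAAAACGCTGAGGAGGGACGTCCCATCATTGTTCGGGCGCAAAAATCCGAAACTCCACACATGGCGGCAATCAAAGACCGGTTACTGCACCGCGAAGTGTGGTACGACGAACAATGCCTTAAACAAGACAAACGTTATGCGATGAGATGCAATATGTTTCGGACGGGACGATTCACTCGCCGCATTATGCGCCGATCAACACTTCTTGGTGGGTCGCAGATTGGTAGTAGGATGTTCTTGAAACTTTCTTCGTATGCCGTTGATAAGCAAATTAAGTCCCAACGTATGGGCGCCCCGACGCCAACCGGTACCCGAGTAAGGAACGCACGGCTGAGTCTAGGATTGAACCGCTACCCCCTCTATTTCGATTCCCATCCAGACCGGTTCTTGGCTCCAGGACAGGCTCAGTTTAGAAAGAAAGCGGCCGCACAAGGACACAGGGAAAGAATCGTCACTCCAACTGCCCAGCATCACGTACAACATTATAAGTGCTGCTCGGTAGACCCGTCCGAAATCGAATTCACAGCGACTCGGAGAGCTGTTAAATGCGGGCATGCTCGGAAGATCTTCGAATGGACTATGGGTGCCCGCCCCGGGCAGTGTAGTGCGAGGAAAATTGCGGAGGTTAGTTGCTCCGTTGCAGGGCCGACCTCCATACATGCACAGACACCATGGTTGCGCCGAATGAATGGAGTTCTCGTCGGAATCTTAGAGATGGACACGAAGCGCTTCCACGCCCCCCCTGGGCCAGGACCGTACGGTTCTAGGTCCCAACAAGATTTGGCTGGTCGTGAACATGGTCGCATGCGGCAGCGTGAATCGAATCTTCCTGGACTTACGAAAGATGTTGAATTTGCCGAAGGG
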