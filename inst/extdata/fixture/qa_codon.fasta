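>qa_g1
TACTCTTCGGCCTTCCTACGGACGAACATTAAGTTCTTGCGGGGAATGACGAACGTCCGGGTGCCTGAACAAGAACCGCGTTTAAAGGGATTACGCCGTCAAGATAGACGTAATACTGTGCCGATAGAAGACGCGTACGAGAGTCCGTGCACGATATGGGGTGACGCTCGCCGACACCAGACTGGTATTAGAACCAGGACGTGGATATGGGGTCCAGCTAGGACCGAGGCCCATGTTTACATGTACCCCGATCGCGTATACTGTATGTATGGCCGTCAAGGTAGTTTTTATGCACGCGATGTGTTTAGAGGGACCTTCTTCGTCGTCTACATTCTACTGAATGTCTTCTGGATAATCCGTCGAAGTTTCTGCCCTTGCATGCTGTGCTGCCGGAAACAAGCATGTGGCTATGCTGTTTGTCTTTATCTGCGAATCCTTTATCCTCGGTGTGACCAGGGACTGGTCGTTATAGACCAAGCGCAAACGAGCAACATGTGGAGTTGGGCTAAGAAACTGCATAGCGACCCTCAACCAGACAGCCGAGCGGGCGAGCTAAATCAAGCCGGATCCCTGGAGTGTGATTACGGAACCGCAATAGCATTCCCAGGTCACAAAACTCCCGCTAAGTGGCGGCCGCCACTGACAAAGGACGTAGGAATACACTTGCTTTCTCGGTGTACATGCCCCGCATCACCAGAGCAATTCAGTAGACTGAAACCTTCAAAAAAAGTGCACGATGAAAACTGGCAACACTCGTACCGCTTCAGGGCCAGGCTGCACTGGGGGTGGATGGGTTGTACATCTCGCCACAACGAGTTTGTACTTTTAGATTGTGCTTTTCCAAGATGGGTTCGTGTCTGTGGGCCTCGATACAATGCGCTTTTCGCGTATCGCCGTGTG
>qa_g5
TACTCTTCGGCGTTTCTACGGACGAACATCAAGTTCTTGCGGGGTATCACGAACGTCCGGGTTCCTGAACAAGAGCCGCGCTTAAAGGGATTGCGCCGTCAAGATAGACGTAATACTGTGCCCATAGAAGACGCGTTTGAGAGTCCGTGCACGATATGGGGTGACGCTCTCCGGCACCAGACCGGTATTAGATCCCGAACGTGGCTTAGGGGTCCAGCTTGGCCGGAGGCGCATGTTTACATATACCCCGATCGCGTATACTCTATGGATGGACGACAAGGTAGTCTTTATGCACGCGATGTGTTTAGAGGGACCTTCTTTGTCGTGTACATTCTACTGAATGTGTTCTGGATAATCCGTCGCAGTTTTTGCCCTTGCATGCTGTGCTGTTGGAAGCAAGCATGTGGTTATGCTGTTTCTCTTTACCTGCGGATCCTTTATCCTCGGTGTGACCAGGGACTCGTCGTTATAGACCAAGCGCAAACAAGCAACATGTGGAGTTGGGCTAAGAAACTGCACAGCGACCCGCTACCGGACAGCCGGGCGGGCGAGCTAAATCAAGCCGGGTCCCGGGAGTGTGATTACGGAACCGCTATAGCGTTCCCAGGTCGCAAAACGCCCGCTAAGTGGCGTCCGCCACTGACTAAGGACCTAGGAAAACACTTGCTTTGTCGATGTACATGCCCCGCATCACCAGAGCAATTCAGGACACTAAAACCTTCAAAAAAAGTGCACAACGATAACTGGCAACACTCGTACCGTTTCAGGCCCAGTCTGCACTGGGGTTGGATGGGTTGTACATCACGCCATGACGAGTTCGTGCTTTTAGATTGTGCCTTTCCAAGATGGGTTCGTTTCTGTGGGCCTCGATACAACGCGCTTTTCGCGTACCGCCGTGTG
>qa_g6
TACTCTTCGGCGTTTCTACGGACGAACACCAAGTTCTTGCGGGGTATCACGAACGTCCGGGTTCCTGAACAAGAGCCGCGCTTAAAGGGTTTGCGCCGTCAAGATAGACGTAATACTGTGCCCATAGAAGACGTGTTTGAGAGTCCGTGCACGATCTGGGGTGACGCTCTCCGGCACCAGACCGGTATTGGATCCCGAACGTGGCTTAGGGGTCCAGCTTGGCCGGAGGCGCATGTTTACATATACCCCGATCGCGTATACTCTATGGATGGACGACAAGGTAGTCTTTATGCACGCGATGTGTTTAGAGGGACCTTCTTCGTCGTGTACATTCTACTGAATGTGTTCTGGATAATCCGTCGCAGTTTTTGCCCTTGCATGCTGTGCTGTTGGAAACAAGCATGTGGTTATGCTGTTTCTCTTTACCTGCGGATCCTTTATCCTCGGTGTGACCAGGGACTCGTCGTTATAGACCAAGCGCAAACAAGCAACATGTGGAGTTGGGCTAAGAAACTGCACAGCGACCCGCTACCGGACAGCCGGGCGGGCGAGCTAAATCAAGCCGGGTCCGGGGAGTGTGATTACGGAACCGCTATAGCGTTCCCAGGTCGCAAAACGCCCACTAAGTGGCGTCCGCCACTGACTAAGGACCTAGGAATACACTTGCTTTGTCGATGTACATGCCCCGCATCACCAGAGCAATTCAGGACACTAAAACCTTCAAAAAAAGTGCACAACGATAACTGGCAACACTCGTACCGTTTCAGGCCCAGGCTGCACTGGGGTTGGATGGGTTGTACATCACGCCATGACGAGTTCGTGCTTTTAGATTGTGCCCTTCCAAGATGGGTTCGTTTCTGTGGGCCTCGATACAACGCGCTTTTCGCGTACCGCCGTGTG
>qa_g2
TACTCTTCGGCGTTTCTACGGACGAACATTAAGTTCTTGCGGGGTATCACGAACGTCCGGGTGCCCGAACAAGAGCCTCGTTTAAAGGGATTACGCCGTCAAGATAGACGTAATACGGTGCCAATAGAAGACGCGTTTGAGAGTCCGTGCACGATAGGGGGTGACGCTCTCCGGCACCAGACCGGTATTAGATCCCGAACGTGGCTTAGGGGTCCAGCTTGGCCGGAGGCGCATGTGTACATATACCCGGATCGCGTATACTCTATGGATGGACGTCAAGGTAGTCTTTATGCACGCGATGTGTTTAGAGGGACCATCTTCGTCTTCTACATTCTTCTGAATGTGTTCTGGATAATCCGTCGCAGTTTTTGCCCTTGCATGCTGTGCTGCTGGAAACAAGCATGTGGTTATGCTGTTTCTCTTTACCGGCGGATCCTTTATCCTCGGTGTGACCAGGGACTGGTCGTTATAGACCAAGCGCAAACAAGAAACATGTGGAGTTGGGCTAAGAAACTGCATAGCGACCCGCAACCGGACAGCCGGGCGGGCGAGCTGAATCAAGCCGGGTCCCGGGAGTGTGATTACGGAACCGCTATAGCGTTCCCAGGACACAAAACGCCCGCTAAGTGGCGTCCGCCACTGACAAAGGACCTAGGAATACACTTGCTTTGTCGATGTACATGCCCCGCATCACCAGAGCAATTCAGGAGACTAAAACCATCAAAAAAAGTGTACAACGATAACTGGCAACACTCGTACCGTTTCAGGGCCCGGCTGCACTGGGGGTGGATGGGTTGTACATCACGCCACTACGAGTTCGTGCTTTTAGATTGTGCTTTTCCAAGATGGGTTCGTCTCTGTGGGCCTCGATACAACGCGCTTTTCGCGTACCGCCGTGTG
>qa_g3
TACTCATCGGCCTTCCTACGTACAAACATTAAGTACTTGCGGGGTATAACGAACGACCGGGTCCCTGGGCAAGAGCCGCGTCTAAAGAGACTATGCCGTCAAGATAGACGTAGTACTGTGCCGATAGAAGACGCGTTTAAGAGTCCGTGCACGATATGGGGTGACGCTCTCCGGCACCAGACTGGTATTAGATCCAGAACGTGGCTTAGGGGTCCAGCAAGGCCTGAGGCGCATGTCTACATTTACCTCGATCGAGTATACTCAATGGACGGGCGTCAAGGCAGCTTTTATGCACGCGATGTGTTTAGAGGGACTTTCTTTGTTGTCTATATTCTACTAAATGTCTTCTGGATAATCCGTCGCAGTTTCTGTCTATGCATGCTGTGTTGCTGGAAACAAGCGTGTGGTTACGCTGTTTCTCTATACCTGCCTACCCTGTATCCTCGGTGTGACCAGGGGTTGGTCGATATAGATCAGGCGCAAACGAGCAACATGTGGAGTCGGGCCAAGAAACTCCATAGCGACCCTCAACCAGACAGTAGGGCCGGGGAGTTAAATCAAGACGGCTCCCTGGAGTGCGATTATGGAACCGCTATAGCATTCCCAGGTTACAAAACGCCCGCAAAGTGGCGTCCGCTACTCACAAAGGACGTGGGAATACACTTGCTTTGCAGGTGTACATGCCCCGCATCACCAGAGCAATTCAGGAGACTCAAACCTTCAAACAAAGTGCACGACGAAAACTCGCAACACTCGTACCGATTTAGGACCAGGCTGCACTGGGTGTGGATGGGTTGTACTTCACGCCACAACGATTTCGTTCTTTTGGATTGTGCTTTCCCAAGATGGGTTCGTTTCTGTGGGCCTCGATACAACGCGCTCTTTGCATACCGCCGTGTG
>qa_g4
TACTCATCGGCCTTCCTACGTACTAACATTAAGTATTTGCGGGGTATAACGAACGACCGGGTCCCTGAGCACGAGCCGCGACTAAAGAGACTACCCCGTCAAGATAGACGTAGTACTGTGCCGATAGAAGACGCGTTTAAGAGTCCGTGCACGATATGGGGTGACGCTCTCCGGCACCAGACTGGTATTAGATCGAGAACGTGGCTTAGGGGTCCAGCAAGGCCTGAGGCGCATGTCTACATTTACCTCGATCGAGTATACTCAATGGACGGGCGTCAAGGCAGCTTTTATGCACGCGATGTGTTTAGAGGGACTTTCTTCGTTGTCTATATTCTACTGAATGTCTTTTGGATAATCCGTCGCAGTTTCTGTCTATGCATGCTGCGTTGCTGGAAACAAGCGTGTTGTTACGCTGTTTCTCTATACCTGCGTACCCTGTATCCTCGGTGTGACCAGGGATTGGTCGATATAGATCTGGCGCAAACGAGCAACATGTGGAGTCGGGCCAAGAAATTCCATAGCGACCCTCAACCAGACAGTCGGGCCGGGGAGTTAAATCAAGACGGCTCCCTGGAGTGCGATTATGGAACCGCTATAGCATTCCCAGGTTACAAAACGCCCGCAAAGTGGCGTCCGCTACTCACAAAGGACGTAGGAATACACTTGCTTTGCAGGTGTACATACCCCGCATCACCAGAGCAATTCAGGAGACTCAAACCTTCAAAAAAAGTGCACGACGAAAACTCGCAACACTCGTACCGCTTTAGGACCAGGCTGCACTGGGTGTGGATGGGTTGTACTTCACGCCACAACGATTTCGTTCTTTGGGATTGTGCTTTCCCAAGATGGGTTCGTTTCTGTGGGCCTCGATACAACGCGCTCTTCGCATACCGCCGTGTG
>qa_g7
TACTCTCCGGCATTCCTGCGGACGAACGTTAAATTTTTGCGGGGGATGACAAATGACCGGGTGCCTGAACAAGAACCTTGTTTAAGGGGACTACGACGTCAAGATAGACGGAATACTGTGCCAATAGAAGACGCGTTTGTGAGTCCGTGCACGCTATGGGGTGACGCTCTCAAGCATCAGACCGGCATTAGTTCCAGAACGTGGCTTAGGGGTCCAGCTAGGCCGGAGGCACATGTTTACATTTATCCCGATCGCGTCTACTCTATGGACGGACATCAAGTCAGTTTCTATGCACGCGACGTGATCAGGGGGACTTTTATTGCCGTCTATATTCTGCTGAATGTTTTCTGGATAATCCGCCGCAGTTTTCGCCTATGCATGCTTCGCTGCCTGAAACAGGCATGCGGTTATGCTGTTTCTCTTTACCTGCGCATACTGTATCCGAGGTGTGATCAAGGACTAGTTGTCATGAACCAAGCGCAAACCAGCAATATGTGGGGTTGGGCTACGAAACTGCATAGCGACCAGCAACCCGGCAGCCGGGCTCGTGAGCTGTATCAAGACCGTTCCTTGGAGTGTGACTACGGCACCGCTATAGCGTTCCCAGGTCACAAAATGCCCGTTAAGAGGCGACCGCCACTAACAAAGGATGAAGGAATACACTTGCTGTGTCGGTGTACATGTCCAGCATCGCCAGAACAGTTTGGGAGACTTAAGCCCTCGAAAGAGGTACACAACGAGAACTGGCAACACTCGTACAGATTTAGGGCCGGGCTGCATTGGGGGTGGATAGGTTGTACATCACGACACGACGAGTTCGTTCTTTTAGATTGTGCTTTCCCAAGATGGGTTCGTTTCTGTGGGCCTCGGCACAACGCGCTCTCCGGGTACCGTCGTGCG
>qa_g8
TACTCTCCGGCATTCCTGCGGACGAACGTTAAATTTTTGCGGGGGATGACAAATGACCGGGTGCCTGAACAAGAACCTTGTTTAAGGGGACTACGACGTCAAGATAGACGGAATACTGTGCCAATAGAAGACGCGTTTGTGAGTCCGTGCACGCTATGGGGTGACGCTCTCAAGCATCAGACCGGCATTAGTTCCAGAACGTGGCTTAGGGGTCCAGCTAGGCCGGAGGCACATGTTTACATTTATCCCGATCGCGTCTACTCTATGGACGGACATCAAGTCAGTTTCTATGCACGCGACGTGATCAGGGGGACTTTTATTGCCGTCTATATTCTGCTGAATGTTTTCTGGATAATCCGCCGCAGTTTTCGCCTATGCATGCTTCGCTGCCTGAAACAGGCATGCGGTTATGCTGTTTCTCTTTACCTGCGCATACTGTATCCGAGGTGTGATCAAGGACTAGTTGTCATGAACCAAGCGCAAACCAGCAATATGTGGGGTTGGGCTACGAAACTGCATAGCGACCAGCAACCCGGCAGCCGGGCTCGTGAGCTGTATCAAGACCGTTCCTTGGAGTGTGACTACGGCACCGCTATAGCGTTCCCAGGTCACAAAATGCCCGTTAAGAGGCGACCGCCACTAACAAAGGATGTAGGAATACACTTGCTGTGTCGGTGTACATGTCCAGCATCGCCAGAACAGTTTGGGAGACTTAAGCCCTCGAAAGAGGTACACAACGAGAACTGGCAACACTCGTACAGATTTAGGGCCGGGCTGCATTGGGGGTGGATAGGTTGTACATCACGACACGACGAGTTCGTGCTTTTAGATTGTGCTTTCCCAAGATGGGTTCGTTTCTGTGGGCCTCGGCACAACGCGCTCTTCGGGTACCGTCGTGCG
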