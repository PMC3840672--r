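>rrna_ssu_synthetic 18S-like synthetic reference
GGTTAAAAGAAAACGGCATTTGAATTTTCACTTTACCCTTAGACCCACTACATCGGATTTAGTCGGGAGGTTGCAATAACGAGGGAACTGTTTGGCCAGGGGTAGAGCTGGCTTTCTAGCGGGTAGTGATATAGATCACGCAACCAAAACGGTCCGTAGTTAAGATGCGTAAACAAGTTTCGCTTTGAGGCGTCCGGCGAGCAACCTTGATCATGCCCGCCCAGGTAAATGCGGTGCTTAGCCTCTCGTCGTACGTGGCAGACGATTGATAGCGTATTTATGTGGCTGTTTAATAAAGTGTTTGTGATGGAAGAGAGCTCTAGACTTCCTGGATGTAAACACAGGCGCACATCGACTCTCAAAGGTTACCTGGTTGCTATAAGCATAAAGTCATGAGCGGAATCGTCCGGATGAACCAAACGACTAAGGAGGTGTCTCGCCACATATAACGAAGTTAATCAGGATACCATTCACGGCGTGGCCGAGCTGCGTGGCTTAGAGGTTCATCCGAACAAAGGCACCAAACACGTACGGACACAGTCCGGGTAGAACGGCCGTGTAAACAGGTGTTCACCGCCGAGGGGTAAGGATCAAGACCCAGCCTATTCTCCGAGTGGCTACCTGGGGTTAAACGTTACCGCGGAACTAGTTAGTGCAATGCAGTAGTCTAAACATGGCGCTTTTTTGGAGCTGGTCGACCCAGTCGGTTCATCACACCTTGGGCGGAATATTGCAGCTTAACACCCGTCCTCGTTCACGGCGAAGACACGTTTGCGGTGATAAACCATCGGTATAGACAAGCGCGCACGCAATAACGTTGGTCGAAGTGGCTTGGAAGCATAAGTTCACACGTGGAAGGGAGGTACGCGTCGGGACAGTGAAACCATCCTCTGCTCATCTACAATAACCACATTCCGAGCATTTCGAATTGGGATGCCCAAAGAGTGGGGTGCAAGCTGTGGATGCTACAGCTAGCGGAGTTATGCATGGAGCCGGTGATCTAACATGTGCAATAGCTGTACACACCGGTGGGATGTTGAATACTATGTATAATCTTAAACATAGCAGGTTCTCTTTCAGCGAGAGTATTTCAGCTCTGTATCTCGATACATTTCGTACGGGCCGTGCGGAGTGCAATCGCTAGACCCGTCTTGATAGTACCCATGAATGTCCTAATAAATAATTGAGGGAACGTCCACTCTAGCATTGATCAATTATTTGACGAGAAGATTAAGTTTAGCCGTGATGCCGACTAGAGTGGGGATTGGACTTAGTTCTGACTCTATTAGAATAATAGAACCCTGGAGAGTATCCGCATATATAACCGTTGGGAGAAGTATGGCACGGCCACGGAATGGATTCTACAACTCAGGTCGGTGGGACACGACTCGTGCATGGGAGGGCGGGCGCGTAGTAAACGACCAGTCTCTCGTTTTGCTCTCAACATTACTTACAATAGTTCCGGCGGTTGAAGATTCGTCTTCTGCTCTCCCAGAGGGTATGTCACCTGGACATTTGAAGTAAAAAGACTTTCGGTCCACCACCAGACCATCGGGAAAGCCTTCTCAGTCGCCAGGTTAAATAAACGCCTGTTTTGAAAAGTGGAGTATGCTGTGCAAAATATCACTGGTCTAGGGGGTACCGCAGCGAGTCGAGAAGTCGCAGCACTAGGTGGAACTACTGGCTATACGATAGGGCGTTTTCGAGGGAAATGTACTAGCCACGCTGCATGAGCTTGAGCAAGGGTTAGCGTCTCGTTTTGGAGCCCCATCTGCAAAGATCTTCTCTTTAGCCACGTCA
>rrna_lsu_synthetic 28S-like synthetic reference
GTCCTTAAAAATATTGACGATCCTGCTATCCTCATCAACGGGGTTTTCTGAATTGACAGCCTAGTTGCACCGCTTGCTGCACCATAACATAGTAAGGTGCTAGCGAATATTGGCCGACGAGACCGTGCGCTAAACAATGCCCGCTCGATTGATAAGGGTTTTACCCACGATGGGTGTCAATACGACCTCAAAGTTGGGCGATTGGGGGGTTGGTACCGGCCGAGAAGGCATTGCATATCGGACCCTAACTCACCGTATACGCGCAAAATTTATCCTACATGGCCTTTGGATAAGATAATCTACGTCTACAACGGAGAGCAGTCATCGGCTGGTCTATTCGAGCGCCCGGGCATTCATGCCATCACGCGTTTTTCAGAGTCAACAGTCCAATGTATCAAAACATGGGGGTGGATCGATACTCATTCATTACACTTCGGGTTATACGGCACGTGATACTTTTAGTCGCGTTCTAGTAGAGTTGGCCATGCGCGCTAGGGCTAAGACACTAGAGCCAAAGAGCTTAGAGAATAGTTATAAGTGTCAACACAACCGCAATTGTGCGTCCGCGTAGCGTCCGCTGGGTCCGCTCGTCCGCACCGCCAACCTATCAAGTGCTTAAGGAGAGTCAAGTACTGGGGAGTCTGCGGACTATTACCCTAAAGGAAGTCTGACAATACTACCGAAGAGTACCGCGGTATGATGCAAACTAGTATGGCGTATACTACCCCCTCGATCACAACGAATGACTTATTACGCCTTAAAAGAGCAGCTGAAAGGGGAACCGGCTTTGAATAATAGCGTCCCCAAACGCCGTTCTTAGAACTGCCACGCATTAAACGAGATCGGACGTGTTCATGCCCTGAACCATACTGCCGACGCGGATGCTGAAGAGAGCCACATAAGATGGATCAAATGACCGGGTATACCTTAGACTTGCAACGGCTTGGATCTGACGGATTATGAGTAAAAGAGATTGTTGATGACCGCCTAACCCCCAACGATTAATTAGTCACAGCTTTCACCCTACCGGGAAGAGCCGAGCAAACGCCACACCTCCTCCAGTCCTCGAAACGAAGGAAGGATTTCATTTTCATGCACACTAAGGCTACCAGGTACTAACGTGTACTGGATCAACAGAATCGGAAGTATAAACTTTAGGGCTTAGTTTCCGTAATCGGGGCAGGACACGGTCATGCGGTAGACTCAGGGCACACTGCGTCCTCATATCTAGAGGTTACGTCCGGGACAATCACCTTCGTGCGACAATTCTTCATGATCTCTAATAGATCCACCGGTGACGTTGACTCGGGCAGCTGGTGGCCGTATAGGACCAATATGCGATAATTCACGACCCCTTTGTAGGTTCTCAGGTTTATCCATGTCTGGTAATAAAGAAAGATACCCGTTGAGCGAATATATTGGTTGAGTACTCGATCATAACATGAGCACCTCCGAGGGCCATCGGTACGGTAAAACGTATATTGTCTCTTCCCGGAGGCCACGTAGGAGAGGCTCCTGTGACGTGGCACACGATTCCTCAAACTAACGATTAAGTCAATCCACTTCGTGCTCTTGATTGTGTACCATCAATCTTGTCATTTCTCTAGATGACCAGAAAAATGTGCATATACGAGGACGCTATCTATTGGCAACACACGTGAAGTCCGATTTGGAGCATCTTTTCCCGTGGATATGCTGCCTGTTGTCTGGTCCTAAGAATACACAGAGGGCCACAGACAGACTGACACTAGTGCCGGTTGAGCCACTAGGCAAATGGTCGGCCGGAGGCCCATCAAGGTCGGGCGTGTCGGATTAATATTGGCGGCGCGGGGGAAGTATTACTAGCATATATCGGTAATTACAACTTATGTTCATGCTAGGGTCTTTGCGCGTTCTTTTCCTGCCCACACTTCCTGGTTACACCGTTTGATCGGGTAGGTTGGAAGGCGGGAGTCAGTATCAAATTCCAATAAAACACTGCTGTGTTAGTATTAACTATACCAAAGTGCACGTACCTATACTAGTCGGTGGCCAGGTTATCGGCAATAGCATGGACCTGAGAAGGGAATCCCCTCCGTAGAAGCACAATATGCGGTATCCCAGCAGAGGCTACGCGATACTTCTTACAGTGTTCACGATGATGGCTCTGGATTGATCTTCCGCGCGTACTGTTTCGTTCGTAAGACAGCAAAGAGTAACCTGCATATGCATAAATCTAGGCAGAGTGCTGCATAGTTCCCGACGAAACTTAATTACGCCCCTGCCACCAAGCCCAGGACTCATGATTATCTTCAGGGCATAGCTCGTGTGAAGTACTGTGCATTTGTCATAAGCAAGTTTAGGGCTATTAACCTCCGTCCATTTAACCGACAAGGGTGCGAGGAGCATGCCAACGCCAGAAATGGGGCTGAAGCGCCCGGCAGCATTAGCCGTGACGAAGAATGACTAGGACTCAATGAGGGCAAAACTATAACTATAAAGACGTGAGGGCATGGGGAGCACTGTCCAACCGACTTGGAGGCAGGGGACTGAACCAGCTCAACACACATAGCGGTGGTCGAGCTCTAAAACCAGCGCAACGGTCCGATCTAGTCTTCTTCCGTCACGTTTGAGGGCTTTTGATAGGTGTACCAAACTAATGGAGAATGATCATGAATCTGTGATACATTTCTTGCACCTCAGCGATATCAGGACGGACGAGGAGTTGCCATGAGGGTGGAGTCGGACTGAGAATAGGTTAGAATACCGTTTTAACTTTGAACTAGCAGTAATTTCCCGCCATTCATCCAAATAGGATACCTAAGAGTGATCTCGGCCGAAAAATACCGCAGGTTTTCGGGCAATAATCAGGGAATCCACTAGCCCGAGCTAATTTGGAGTTTCTTATTCTGGCGGTCAAGAGACGCCCTTAGCGACTAGATCACGTTTGAATCATTATCCTATTAACGCTATGGGCGGCTAGCCCCAATACGGGGTGAAGCATCCGTTAGGCATTAACCTACCACCGTTAAGAAGTTTACTTTAAGCTGCGTTGACCTCAGCCCACGCCCCTCGTTGGATTGAGCGCTCATACACTATGTAAATGTAGATGTTATCGGTACTGACTTCTCGTCGGAGAATTGCGACTTAATGGCAGACCGTCACATGCCATGTTCCTTTCGGTGAATGCTGCGTGAGAGCGCGTCCTCCCCATAGTTCAC
>rrna_5_8s_synthetic 5.8S-like synthetic reference
ACAATCGTCGAAGTAGTGTGAATAACTGACAGACATCGACATCAAGGACTTTGACAAATAACCCGAGGCTCATAAAGATGAACGGAGGCAGTAAGGTATATGCTTATGACTTCATGGCGTCGTGGTCAGAGCGCGTACGTAGTGGAAGATGTCCTCCTTA
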