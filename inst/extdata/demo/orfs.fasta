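>G001 synthetic ORF
ATGAAAATACAAAAGGGTTACAAAATGGTCAAATTTACGAGTCGTGGGCGAACCCATGGAGCTATCCAGACATCTATAGGTTTTTGCAAGGGTGAGCACACTCTCAAGAGTCCCACCTCGGGGAGTTGCAAAAGCCTTATGGATTCGTGGACCCATACGATTTTCGCGGTCTGCATATGTACCCGAGCCTCAACCGGAGTGACTTCCGCCATCGCCCTGTACTGGTCGGGGTGGCTTAGCCCGCATAATGTTGGAATTCGCGGCGTAGCCTCTACCTTCCTTGTAGCGTTACTGCCCGCAGGAGGATTTGGGGCGGCGACCGTATTGCCGACACGTTGCCCGCGCGTTCGGCACGGTGCGGTTGTCTTGAACAGGTAG
>G002 synthetic ORF
ATGGCGAAGTCGAAGTCATCACTCGCTGAAAGTTATAATGCCAAGAGGTACCAACTCTCGGGGGTTCCAGACCCGATTAGATCCAAAAAGCTTACACTCAACCTCCAATTGCCAAAGTGGCAAACTGCACTCTTAGGGGTCCGTTCATACTCGGTCTCCCCGATAAGGGTCCTCGTGATGGAGGCTAATCCACCGAGTGGGAGCTCACCAGATCTCCTCATGGTGCCAGTGGGTACGATCTAG
>G003 synthetic ORF
ATGAGGCTGAAGACGGCGTCCCCACTTGACTTGGGCTCTGGAGCCTGCATAGTCCAAGATAGCCATACGAGTGTTGGGCATAGCGGTGGTAAAGGGAGCCCAAGGCGTGTTAAAAATACCATGTGGAAGCAGCTTTGTTCCATGCGTTGTTTTATCAGACCAATACCCCAACATCCACCGAACCACCTTCCGTCAACGCCCAAATTACATGGGGGTGCCGAACCTTGCTCATGGCGTGTAGGTAGGATCCGTGACTGCCCTGTTCCTACGCGCTTTCTCTCGCTATGGTATAACGACGATATGCATGGCTCAGAAGGCACCCATAATAATCACTTTAAGTCACCTTCGGGCGCATATCACGGGTGGTATGAATATCCCGTAGACGTACTCTTAATACTTTTTAAGCGGGCGGGCTGCTGCTGCGGGGGTCTTTCCTAG
>G004 synthetic ORF
ATGCAGTGGGAGATCAAAAGGTGCTCGCGTACAAGGACCATGGTTCCTAAGTCATATTGGCGCATTGGGGGTCGTTCTGAGGTCTTTGCAACGCATTACCTGTTAACTAGCATCGTTTTGACCAAAATCAGCGTAATCGAGCTGCTGGGGTGTGAGGCTCGGCCCGCAAGGTCTCGAACGGAGACCGACCCAACAGACCTATCCAGTACTGACGTCTCAGGCACTAGGTGGTACTCAGAGAAATGA
>G005 synthetic ORF
ATGGGCCTTAGACTCAGTCGAGGTAAACAAGAGAAGCTTCCGACTTGCACTAAAAAGGCCCAGAATGGCTTGCGTTTTTGCGAGATCAAGTTGTACCCACGCCTAATACGCATGCAGCCTCCGGGTTATGCCGGGCGACACTCTTGCCCGGACCGTCTCCTAGAGCTCCGAAGGACTCGCGTTTGTTTAGGAACAACACATCCCCAGCGAGTCAGAAGACAAGTAAGGCAAAGGATGCGGTTCCCACCTTGCTGGACGCATCCGCCCGTCCCCGAACTCTGGTAA
>G006 synthetic ORF
ATGAGATATCGAGGCCGTTGGCCTTCGTATAGATGGTTCTTCGAGCCGGGTGCGAAGTTCGTGCACTTATGGGTCTCGGCTTGTGACGTGATCAAAACGCCGGGAGAAAACCATGGTGTAAATCCTCTCGCCCCTGCATCGCTGGAGCGGTGCTCGGTTGCGTGTACTTTTGTATTCGGGGTGGGGGGGTGCGTCAATTGTGTGGCACGGGCCTCAAAGGACGGTACTTTCCCACAATTGGTACGTATTGGATTCGGGTCTCCATATCCAGTTCACTATGAGTCGCGTCTCCAGTATGGAAGCTGCCGCGGTGAGTATTGCTCCCAACCAACAAAGCCTAGCCCAACAAGACGTCTAAAAATGCAAAACTTCGCTTAA
>G007 synthetic ORF
ATGCGGAGACGTGCTGCCGTTCTGAAGAGTAACGTATCTGGGAGTGGCCGCGACCGCGACGCCCTTCTTCTTAAAGGCAATGGCGACAGCCATGGTCGCGCGGTTTCCGCAATGAAAAAATTAGAGGAATGTGTCTATCAAGTCCTGGTTCATACAGGGCGAGTGACAGATAAGCTACAGTGTTTACAATCGCGTCCTCAAGGGTTGTGTTTAATCACTCTGGCCGAAGAGTCTGTTTCTAACGAGGCATAA
>G008 synthetic ORF
ATGTCGGGGTTGCTCTATGGCCGACCGGCGTTAGTAAATCGAGATCGGCGATTAAGCGGACTAAATGCGCAACGCCCGTGTTTACGTCTTTGCTTTGTTGTTTATATGCAGCTGTCCTTACCCACGGAGAGAAAGTACCTTCACGCAACCGGAGCTTATTCCAATGATACTCGTTGCCTCCCTGAACGCACGAATCTGGGTATGAGGTGCTGTTTGTCATGCTTGGCGGGCGACCGTCTTGACATAAACCCGCCCGGGGAGCGGTTGCAGTCGATCGCAGAGTGGGTCTCTATTGCATTAAGGTCTAATTGCGTTTGCACACGTGTGACTAAATGGGTGATACCGGTCGAAAACGCGAGACAGCGCGGGCCGTAG
>G009 synthetic ORF
ATGGCGCCTCAACTGACTAAATTTTCACAAGTTGTAAGTGTATATAGCTCCATGGTTCGCTTGCTGAAGCGCTCTCACAGGCTAAAGTTTTGTGAGAGCCCGGTCACAAACAAATGCCAGTACCGAGCCATCGATACCCACTCGATGTCTGAGTCAATCCCTGTTACCGTTCAACTCCTCCAATGGGGGTATTGGGACTTAACTTCTGTGCCTATGCTACAGCAATCGGGTTCTTCATCGTGGAACTGGTACCAGTGCCAAGACTCCCGAGCAGTCACTCTCATCAAATGTGGCTAA
>G010 synthetic ORF
ATGTTCGAAACAGGCAGGCGTGTCGTGACGTTCAGCGTAAGGTGCTTCCGACGAATGGTTAAGTCACACTATCCTATAACTATGGCTTGCGAACTGTTTGCCATACTGCCAAGATACCATCCGCATGGTAATTACTTAAAACCTAGGTTTTGTTCACATCCCTGGCTGGCCTTGTATGCAGGGGAGTTCGTCTTCACTACAGAGAACCCTGGTTGGAGCCCCCGGCCAGCTGTTAAACCGAAAAGATCCCCTACTGTTACTGGCTCTTTAGTCGGCTGCAAAAATGTAAATTCGAGTCCCGCGAACCCCGCACATGAGCAGAACCCTAGTTAG
>G011 synthetic ORF
ATGATGAGGCTACCGTTGTTATACCACTTATTTTTGTGGCAATGCAGAGCCCTCGCTGGGTCAAGTAATAAAGATCCGCGCCTGCGCGCCAGAGTGAACCAGCTCCTCGTACCATTCAAACATGACTTGCGAGGTAATGTTACCGACGCGCGAATGGAGATCACCGTAGGCAGGCGAGGGCAAGGTCGGTGTTCGATTGCCAGCGTCCCACCAGTCATTCAATCACTGCGTAGCATGAGGTTTGAAGAATGCCTATCTGGTCACATTCGGCCACGAGAGGAACGAGGACAGATGGCCGCGCCAGGGGTTTGTACTCGAGTTCTATGGGGCGGGGTCACAGCTTTCGGGTCAAGTAATCTTCTTAGCGATCTATGA
>G012 synthetic ORF
ATGGGTCATAATACTTGTTTGAATGAAGCACACATGCCTTTGGAGCTTAAGGCCTGCATTCCCCTTCATTCGCTTCACCTCTTCTCTAACATGTATGGATACCCGTGGGCGGAGCGCATTTTGCTACGGGAGTATACGGGAGAGGCCAGACAAGCCAACCTACTGCTCATAACTTCGCGGGGCGGGCAAGTCATTACTAACTATACACAAACAGTGAGATGCAATAGTCGCACCCTTTTCTATCATTTGGACATAGGTTTTGGTTCGGCGCATACGGTAAGAGGCCTGCAAGAGATTGCTGGGGAGGGGGACCTTCACTCTTGA
>G013 synthetic ORF
ATGTTAAGGTTGAATACGGGCAAGACGGCAACATGTTTACTCACAAGCCCTCAGCGCCGCTCGATTTTGCACCCGCTGGGCGAACTGACCGATTCGTTTTTGGTTCTATACTGGGCTTGGAGCGGATGTCGAGTTCGAAAAGGTGCCGGCTGCCATTCCTTGAATCTAGTAGCACGATTGAGAATCATGATCGAGTGTCTCCGAGCAATTCTCGAATTCAGTAGGGTAGGCTACGAACAAGATCGACAAGAGATTACGCCTAAATTGATCCCGCCCACCGGCTCGATATGGCCTAGCCCCCATATATGGATGCTCGGGTATGGTAACGGATCTCGCCCCTTAATGAAGTCAAAACCTAAACTGCCAGTCACCATTGCCCACGTTTGTTTGCTTCTCTTTACGGATTGCTAA
>G014 synthetic ORF
ATGGCACTTCAGAATTCTCATCGAGCTGAAATTACCACAAGTGACCAAGTCTGGATGTTGGAACTTATGCGCGCGCCATGGTTTAACCTTACCTCTGGAAGCCTACAAGGTTTTAGGCCTAGTGCGCTGCAATTGATTCGAACGGACGGAATAACACTAATCACGGGGCCCAAGCTGCTCGAAATGTTACTACGCTGGATGAAGACTAACTTGCGGCCTATGTACGGGCGCTTCACCTACACTTACAAAGAGAGGTCCTACAGCGTAGTCATATATACTGCTGAGGCCAATCCGGCTCAAGAGATCCGGGTTACAACCTTTGACTCTGTTCCCAGGCACCCATCTGTTATCGTGCTACGCATCACGTGCCGACACTATATGTACGCGCTACCAGCTCACCCCACTTGGGTGTAG
>G015 synthetic ORF
ATGTTCGAGATGCTCGCGTCATCTAAACAATTAACTTATGCTATAGTGCGCCGAGCACAACATTACTCAGAACTTTTTTGTCGTTTGTTGGTGTTTCTAGTCGCCTGCCCGCGAAACTGCTCCCGTGCTTGCCTGAGGACTAGATATTGGATAAGAGCTCATGAAGGAGTGGGCCAGTATGTACCAGACCGGGAGCTTCTGAGCTGCAAAGCTCACCGATGGATAAACTCGATCGAGTGGCGAGCGGACATTCCACATTTTAGAAGTATCATACGCGTCCCAGTACCAGTATGCCCTTATCGGAGACGGGGACGTTTTACCCTCCTCCCGCTTGTCGCGCTATATGGTCCCTCCTTTCCGAAATCGCGCCCATTCCTAGTTAGCAGGTGCGTGGTATACCTTCCTGGAAATCTATACATTTCCTACGTGCATAAGTAG
>G016 synthetic ORF
ATGCCTCGTAAGGGGTCGGACCTTAGTGACGGGCACCAAGGCAGTGCGGAAATGCAGCCTTTAAGGAAAGTCAGAGGATCGACGATTCATGTAATGCTCGGCGCGGACACTGCGTTGACATGCATGCACACAACGTTATGTATTATCATACATCAATCCGTCGAGGGGTTGATAGTGCAACGCGGCAAGTTGGGAATGGCTCCACAGACTCCATTTTTTACGAATGATCGCAGTTCTGCCGTTCTGCTACGATATCATGCTAGGCTCTCTGTACGTCTGCCGGGAAGTTCCTTGCGTGATGCGCTATAA
>G017 synthetic ORF
ATGCAACTACGAACCTGGACTGTCCTCGTGGCAACCGCATCTCTGCCGGCATTCTTCCTATGCCGAGTCGTTGTCTACCTCCGCGCCCCGGGAGCATGCACTAACGTGACGACACCGTGCATCCTACGTTGTGCCGAAAGAATTGACCCTTTCTGGCTATCAATTTTACCTGCGATATCCGGGCCTACTGTCCCGTTTCCGATCAAGCTCCGTCTGCCCGTTACGCTTGTGGCGATTCCCAACGGGAGGACTCAGCTGGTAGTACGAGTTAGCCGTGCATCCACTATAGCTATTCACACATATTATTGTGAGTATGGGAATGCGTAA
>G018 synthetic ORF
ATGTGTATGGGCTTGCCCTCGTGGATCACGTATTGTGCCTACATTTTAATACAGTGCGTGTACTTGAGACATCGCCGTGCGATGGTCATGTATGGGCAGCTAAGGACAGCAGGCACGCTTCTTAACTTCGAACCTTGCGGTGCTATTTGCTATGATAGATTTATATTTCTAGTACCGATCGTCCTGTCAGAACACACGACAACTAAGGTTAAATCCTGCCGATTGTATAAAGACGTTGTAGCGTGA
>G019 synthetic ORF
ATGCTGGCGCGAGGTGCACGCTTAGAGACGCCGCTAACCTCACGTGGAGATCGACCAATGTCTCGTCTAGCCTTCCGCAAGTGCAGTAATAAGAAGGGACGTTGGGCCAGTGGCCCCGCCGTTTATAGGCCCACGTCCACCTTGGGCGTAGATATCATATTGGCCAGAGACATTCGTATGAGAGAACTCGCTCAGCAAAACGCTTTTAGCGTAAGCCCCTGCCACTGGTGCATTCCGACCTCGAGACGCGAGGATCTATCTTCCAGCGTGCGTATCCTGTTACAGGCACGTATTCGACTGGCCGAGATAGCAGTAAATGACTTGTCATTAACCCGTCGTTATGCGCACACCTATTTTGGTCCGTCGCCGGCAAATAAGAGGGGCCAGGGAAAGCCAGACCGGAATAAAGCTGCAATAATATTACGCACAGGGGTTTTGCTGAACTAA
>G020 synthetic ORF
ATGTCGAGATGCGGATGTGCCAAGCGCCTTGCAAACTTAGGAGGCGCAAAAGGGACGAAGGAGACCCCGAGGAGAGCTGATTCAGATCTGTTTAGCGTGGTCCAGACATTTTCCCTGCGTAGTCCCTGGGGTGGAGGCGGTTCACGATGGGATGAGCCAAGGAGACTGTCGTCTGCAACAGGAGCTTCATGTTTATGCCAAACGTCGGTGGCGTCCTTGAGGGCCGATTTTTGCGTCTCCAACCAGCTTAGGGTCAAACGGCATCAATGGATGTTAACACCTACTTTCCGAGGCCTATCCTGGGCCTTTCTACTCGAGGACCTCACTCCGATTTATCAAGCTTACCCCCGGAAGACTAAGCCCTGTTGTGTATGTTATTTCCGCGGTCGCGTGGCCTAA
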