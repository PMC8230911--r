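>MC1R_306ter|context
CGTACGGGTCATAGTCCTCAACACGTGACCCTCGAACCGACCTCTGACATA
>MC1R_M264V|context
TTTGGTTGCACACACCTCCGAAGTTAGAAGACGAAAGGACGATCTGCGAGC
>CBD103_S53|context
TCACTTCGAAAATGAGGTTTTCGCCGCCAATGCTGCTTGGGGGGGCAGATG
>ASIP_S82|context
TACCGTCAGTAGCGCTGTTCTTTGTTTCTGCATTGGCATCCAGATTCGCGC
>ASIP_H83|context
TTCACCCCCTCGTGCAAGGGAAGGTAGTGATTTGATCGACCGCCTACTAAG
>ASIP_R96|context
GCGTGGTATTGAGGCGGAAGCTTTTCGGGCGTTGAGCTAGGGATGGGGTTA
>TYRP1_Q331ter|context
ACAACATTCTCGCCAGGAGGCTAGACCCACTAAACAGTCAATTGATGCGGA
>MLPH_157471_c.-22G>A|context
GATGTGATGTTGCGTATCCTGGCAAGTGTAGCTGCCGAACGAACTCCCTTT
>MITF_SNP|context
CATTGGGGCAGATCACCATCGAGCCACCAATATAGAGTCATCGAGTCAACG
>PSMB7|context
TACATTTTTTCACCGATTAAGGAGAGCAGACGGCATCAAATATGATTAACT
>FGF5|context
GTGTTTGAGTTGTGGGAAATCAACTGCATCGGCATCAGTACTCAGTCAAAT
>KRT71|context
GGAAGAGCTGTGATCCTTATGTAAAATGGGTGATGGGAAACACGATAACCA
>T-Box_C295G|context
ACGCCTTCAGACGGTTAACAAAGGGGGGGTAGTCATATGAATGCCCCACCA
>BICFPJ1062878|context
AGCAGGGGTAAAGAGCATAGTCTACGATATCCTAGAGAGTTGCCCTGTATT
>IGF1R|context
GAATACGGCTTAACAGCAATGGAACGATGCAAATCGCGGATGGACGTCCTT
>CBD103_S54|short
GCCTGAATTACCCCTCATAGCACTTCTCTTTACTCCGGGTCCATCCACGCTTGGCCTGAT
>CBD103_S54|long
GCCTGAATTACCCCTCATAGCACTTCTCTTGGGTACTCCGGGTCCATCCACGCTTGGCCTGAT
>TYRP1_345delP|short
GGTAAGGCGCTTCGATCAGGACACTCGGGTTAGCTTCCCACACAGGTAGCCCTGCTACAT
>TYRP1_345delP|long
GGTAAGGCGCTTCGATCAGGACACTCGGGTCCTTAGCTTCCCACACAGGTAGCCCTGCTACAT
>RSPO2|short
AGGCATCCCGTGTATTCGACAAGTTATTGCCTTCAGGCTTGTCTCTTCTGCATGTCCGGATCACCTGTGC
>RSPO2|long
AGGCATCCCGTGTATTCGACAAGTTATTGCCTTCACTGAGAGCGCAGACGCTGTAATGTGGAAGCTTGGCAAACCTTGATAGTTTACAACAAAAGATAGATGCCTGACGGACACGTGATTATGCCATATATGTGCTGGCGACGATCTATTATATCTTCACTCATCTCCTAAAGTGGGGGTCTTCGGACACGGTCAGCTACTTGGCTTGTCTCTTCTGCATGTCCGGATCACCTGTGC
>ASIP_SINE|short
ACCATGGCAAACACGATTCAGAACAAATCACTGACCTTGATTTGCCTGATCTTCGTGATAACTTGAATTT
>ASIP_SINE|long
ACCATGGCAAACACGATTCAGAACAAATCACTGACCACCACTATGCCTTCGAGCGTGTATTCGCCAACCCACTGTGCCGTCTCTTCAGGAAGCCACTGTATGAAGGATGTTCGCCATAGATAGCGGCCACGCGGTTCTGCCGTGCCTGGAGCTCCCTAACACGCTGCGCAGTAAATTCCTTACGGACGGGCACACTGAGTGAACCATAAACGGCGGGACGGTGCCAGTGCCGGAGACTTGATTTGCCTGATCTTCGTGATAACTTGAATTT
>MITF_INS|short
TCCAGACTAAAGCGTAGAACTATGATCGCTCTCTTGCCTCGCATTGCCCATTGGTGAACCCCTACAACTC
>MITF_INS|long
TCCAGACTAAAGCGTAGAACTATGATCGCTCTCTTGTTAGAAACTCGTGGAGGTAACACCCCCCTCGGCCCCTCCGTACATGCGATTTCTATTGTTTTAAGTATAATGCCCTAGTACTCGGAAGTAGAGGTAAAAAATGCGGGCAGACACCCAGAACACGGGATTGTACGAATGAAATTCAGAGCACACTATACGTTCATGCCGTCCACCCAATTCTTCGCCCGCCTGCGGCAAAAGCCTCGCATTGCCCATTGGTGAACCCCTACAACTC
>PMEL|short
GTAAGTGTGACTCTTTTCGATTCCAAGCTTAGTGGCCCAACGCTATCGTGTTTGATTCGCTTATGAGGGG
>PMEL|long
GTAAGTGTGACTCTTTTCGATTCCAAGCTTAGTGGGTCCTAGACTTCACCCCAAGAGGGGCACTACCTAAATGTCAAGAAGTCCTTCGGTTTGCTGGTTCAACTGTTCAGAGGAGCGCTTCTTATCGTATTGAGTGTCTCAGCGTGAGATCGACATATATAACTACTCAGCAAGTGAATTGCCACATTAATATAAGTTTGGCGTTAATATCATCCTCGGGTTTCGACCTACAAGACCCCAACGCTATCGTGTTTGATTCGCTTATGAGGGG
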