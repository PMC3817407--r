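>P_01_7651
AAGGGGTCTTAAACTAATTGCTGGCAAGGAGTCGCGGCTCTAGTGATGAATGAATGCAGAATAGGTCCAC
CTCGATCCTT
>P_02_2817
CGAAAGGTAGGTGCCTAAGTCACAACGCCGACTTGTTGAATCACCTAGTAAGCCACTGGGAGTTAGAAAT
AGGTAATGCG
>P_03_5771
AACTTTGCTGCTGAAATGGAGGCAGCCTCCTCCTTGGGTACATACCTTGGATCGCACAAAGATTCTCCAC
CGTCCTGTTT
>P_04_8488
AGTACTATTTTGCGCTACCTCCACGGCTGGATGTACACGAGAAAGCCAGCTAAAGCATGGAACTGCGGCT
GGATACTCCC
>P_11_3726
ACGGCTGTTAAACGGCCATCGCCCGACTATCTCCATCGTTTCGGCCTTTAGGTCACAGTCAGGTCTCAGT
CTCGGGTCAG
>P_12_7434
ATATCGCGTCTCTTACAGTCAGGTTTACGGCGCAAGCTGGGAGAGCGCTGTTACCAGGAAAAGTTGGCGC
CCGTGTACTT
>P_13_4177
GACCGAACGAGTTGCTATGTATCTTAGGACCAACCTCAAGTTTAGTAGCACACGCTATCCTTAGCCATTT
CATTTAGCAA
>P_14_8255
AAGCGTGTTTAAGTAGGCACCCCCACGCCTAGTTCTATCTTAAGAACGACCGGCGGGCGTTCTCCAATCA
TAGACGAAGA
>P_15_UP436
AAAATTTTAAAATTTTAAAATTTTACCTTGTGTCATTCTTGGATGGAAATGGGCATCTGCCACCCTCCAG
GTATTTGTTC
>P_16_3622
TGAGCGCCCTCCGGGAAAGAAAATATTCGCGGTGGGAGAACCTGCATAATGGCCACCGCGCCAGCTCCGC
CCTAAATCCT
>P_17_1640
CTTAAGACAATTCTGCTGGGCTGATAAGCTGGCTCCCAGAATCCGCGTTTCCGCCTTCTACAGTCGAATT
CTTGAGATGT
>P_18_2130
CATTTACATGGGAGATCCGTCCTCGAACGTCTCCCCGTGGTTTACATTGTCTCTGTCGCACCCTTTTGCT
GGTGAAAGCC
>P_19_5229
ACCTTGAAATGACATACAGTGAGTTTGTGGGGCTGGACATGGGCAAACTAGGCGGAACATAATTTACCCG
GATTGTCTTT
>P_20_992
TGATCCGGTCATGAGTCCTAATGGAGTAGGAAACTTTTCGAGCTAATAATAAATAGTCACAGGCCCTACG
TAAATAAACT
>P_21_1200
TCGGGGGTTTGTCTCTAAATTCGGTGAACTCGTCTTGTGCCCTCGCACGATCGTTGTGCATCCAACAAAT
CATCAGTAAC
>P_22_7414
TGTGGATTCGACGCTGGAGTGCTGCTGCGATAGAATTTTATAGGATCACAGTTTCTTAAGTAAGAACGAC
TTGTAATACA
>P_23_2025
GCATCTCCTTGCCCTTCGGGAAAAGATGCACTACTTTTATCTTAGCCCCATGCGTCCATATTGAACACTT
TGCTCGACGT
>P_24_1652
GCAACCAATGAAGAGTGCCAGAATCGTTCCCTGGTCTCCCGGAAGTCAGGGGACCTTTACTGGTGTCTGA
AATGACACGT
>P_25_UP4311
AAAATTTTAAAATTTTAAAATTTTAATCCCTTAGGCAGCGCTATTATACATGTCATGACAAATGGGCACT
TAGCGGAAAC
>P_26_3917
GAACGCTCTCAACACCGAAATCATGCATCGCGAAGGTTCAGAAAATCATACATCGATATTTGATTCCAAC
TACTTATAAA
>P_27_6986
TCACTACTATAGTATCGCGACCGGAGCTGTCCGGCGAAGCCGCCGATTCCCGAGCTCGGCCAGTGCCCGA
TCGATACGTC
>P_28_7692
TGAGGGGGCTTTCTAGCTCTAGGATGGCGGGTACGGTTCGGAGAAAGGCAAAGACCAGGTTAAGAGCGAC
CGAAATCATC
>P_29_8580
ATTGCCCGCTGTTTCGTGGTTATTCTATCAATGAAGGGCTATAAATTGCCAACCCCGTATGACACGCGCA
ATCTTGAGTT
>P_30_5012
CACGCATGGCGTGGGCGTCTCCCCACTAATTGCCTTGGATGATCCTATAAGCCTTCCTGAAGAGGTAGTA
TCCAAGAGCG
>P_31_5501
GACTGAAACAACTTCCCACGACTAGGCCCGACCATCATTGTCAAAGAGTAAGCGTTATTCGCCTTCCGGC
ACTCCTATAC
>P_32_1882
CGCTGTACGATGCCAAAGCACTAATAGTACAGCCACGCAGTTGAGAAGTTATTCGAGGGTGATGTACCAC
AGCATACGTA
>P_33_7686
TAAGTCCGCTTAACATGTTATGTGTTAACTAGAGCCATTAGCAGTCGGGGGGTCGTCTACTGGGCGCGCT
AGCCGGTACT
>P_34_6750
GACGTGACAATATGATCATTGATGTGCGAGTCGATGGCCAGGATGGCGTAATTGTATCTTGCGCGTGGAA
GTCGAATGCC
>P_35_9427
CATCACGCACGGTACGTCCGTAACAATAATGCCTACCAATCTCTCGCTAGTCTGATCACAATTGAGGTGT
TTCAGATCCC
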