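>synthetic_amplicon_600 synthetic 600 bp amplicon reference (seeded random sequence; not a real gene)
CAATACGATTGGTTGATAGGGCATTGTCGCAGAGGAGTTGAATAAAGAAAGGCACTGATT
TTTGCCATCCGAGACAATCTGGATATGATGCAATGTTAGGCAGAGGGTGAACTGGGACTC
TTATAAATGGTATTAACCGGGAAGGATTCTTTCACAATGGCTGTGGCCCTTTACTATTGG
CGAGACATTTAAGTTCCGAAAAAACCTCCTAACGGTTTGATGTAATCCGGACCATAGACC
CGTACTTATTGGGGAGGTAACCGTCGAAGGGGATTCCCAATTTTTTCTAGAAACCATAGC
CGTAGCCGTCGATGCTATTACATCGGATAGGTCAGCAAAAAACCTTTTGCCGCTCTTCTC
GAACGCTCGCTCTCAATGTCGACTCGATACATCGCGCACACTAAAGCCTATTCCGATCAG
CACACTCAGAGGCTCTAGGATAATCACTGGAATCGTGATTCTGGGGTAGAATGCTCTATT
GTGGGATTAGAGCTCTTGTCAAACTAACGCCGAAGTACTGCTCTGCTAACTCGAGCAAAT
GAGCATTTGCTTGGGGTCTGCGCCTATACTATTATACTTAAAGATGCTCTCTGGAATTTC
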