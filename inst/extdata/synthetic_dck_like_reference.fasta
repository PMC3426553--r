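>synthetic_dck_like_cds
ATGTCGGAGTGTTCCGCCGGTGCTATGATCGCAGCGCACATAGCCGCCGAAGTTGAAACA
TCACATCTGCCAGAAACGCGAAGCTATCAGACAATAGCGCATGATGAATCTGCAAGTCTA
TGTCGTCGTGCGTGGCTCCTAGTATCAACCAGCCAAACACAATTTTCTCATGATTTAATA
CTGGTGGGAGTCTCGGTTACAACTCTCAGCCCTTTCGAAAGCAGCGTGCTTGTAAGGAGC
TTCCGCTCGTTTCCTTCCTCAATGGAGAGGAGCGGTGAAATCACGGTGGGAGATGGGTAC
CCATCATGTACTTGCACTTCAAACCATCTGGCAATTTGGGCTGTTGCCGCCTCGTGTGAC
ATGAGCGTATCGCCCCATGCCGCGAACTCAGGAAATCCATTCGATAGATGTGACAATTCG
GAGAGTCGTGGAGAGTGCTATAGGACTGGGGCCTACACTGTTGGCGAGGGATTACTCGCA
TGGCAATGCAAAACAACAATGCCGTGGTCAATGTACTATACTAGTTTCCTAGCTTACTCG
CTGCAGTGCCTCCTAGTCCCATCATTAACGACTACGCACAAAAGTATATTGAGTACAGAT
GTTGATAAGCCTGCCTCCACCTGTGAGAACTTCTTCGAACGGTTTTCAGTTAGCGGTTCT
ATCGGTGTTGGGCGGATATCAGAGTTTATACCTCTTATACAGTCAAGTCAGGTACAATTA
CGTGTAATCAGCTCTCTACGTGCGGGGGTTTCCAAGGAGTGGGCTTGGCGGGTATTATTA
TGA
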