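>yfp_cds_synthetic synthetic stand-in YFP CDS; 717 nt; GC 255/717 (35.56%)
ATGTATGCATCGTCAATTCGAAAGGATTTTGCAGCAACTCGACACTTATATAGTAAACCC
CTTCTTAAATATACATTAGTTTCAGCTCACCTATCATGCTATGTCAAATGGTACCGGCTA
CGTGCTGTTTTCGTAACTTGTTACCATCATGAATTCGGTCGGCTTAAAGATGAAACTTTG
ATAAATAGTCTAGGACGGGCCATTGGGTTGACATTCCTTATATTATGCGCAAAGATGTAT
ATCAAAGTGGTTTATGAATTTTTAGTTAACAATACCTACCTATTATTAACTACATTATAT
TTAATCTGGAGTATTATAATTCTGTGTTGGCTAACAATGTGCCCGAGATCTAGTTACACC
TTGACGGCGTATTCCATCTTTTTGCCAATCGTTACAGAATCCACCAGACATCCTACTTTG
ATGGTCAATGCGAATCTTTACAAGTATAACAACTGTATCTTTCATGAAATTTCGTTGGAA
CAATTTGTTATTTCATCACACGTGTCATATAAGGTAACCAGCCTTATCTATTTTAATACT
GGAGTGTCCGAAGCATTGGGTAAATTTTTGGTGGTATTAAGTTTAGCCGCACAATCTACC
CTTAATAGTGTTTCGTCATTAAATATGACAATAACTCTATACACTGTACGCGCAGTATAT
CTCATGCTACATAATGATTTAAAACATGTACTTACCCAAGGTAAATTAACCGGGTAA
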