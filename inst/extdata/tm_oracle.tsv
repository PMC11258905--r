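oligo	tm
TTTGCTGCTTAGTGGACGC	55.3747
GAGGATCTATGGCAGCCGTATGCGAG	62.5355
TAACCTTTCGATCCGTTTTCCAG	55.0816
TTGGCCTGCCTCTGTAGTCATGGTGT	63.3444
AAGTCAAATACTGGGCCTA	49.4200
TATCGAGGCTAACCTGGAGGACTCGAA	61.7709
CACACTGGCGTCGACCTCTCGGTAGG	65.7105
GTGCTTGTGGACGCCCAGCTCATTC	64.2269
CTAATGGGCGATGCAGTGACACCAG	61.6833
GAATCTTTAGAATCGATCCCTTGCT	54.8545
GGTTGGGCATAGTGTTTCGCGCT	62.2317
CCGGCTGTCGAAATAAGTG	53.1081
AATGACGGCTGGGAGCTATCTCCGCCC	67.0777
ATCACTCCAGGTGGTCGATCCGAGA	62.3575
GTCTCCCGTTATTGTGCGGTTAACAA	59.6318
CGGAAGCTGAATGAGGAGCTTAA	56.7270
GCTCGACTGTCTCCACGGTCGTATA	61.4542
GACACGGAGCTTTAGACG	52.0980
TTGGATTGAACTTAGGGCGCGATC	59.4712
CATTGACATAGCAAGGATGAACT	52.9770
ATGGGCCAGGCTTAGCTAA	54.8062
CACGCAAGATTTTCACAAATTTGAGT	55.8605
GCGCCGAATATCCTGCGTAG	57.8715
GGTGCAATGCGGATTCGCTC	59.1588
GACTTCGGTATTTGTTCTTGATAG	51.6915
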