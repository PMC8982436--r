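>synthetic_rho_utr synthetic 3UTR with two planted miR-9a sites
GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCATGCTTAATTGCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGACCAAAGACTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCACACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGTGCGTCCCCTCCCCCGAGATCCCAAAGAGCTATTGTAACTACGCGACTCTGGCTTTAACCGTTGTGTCGTATGCTGCGCGAGAGGAAA
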