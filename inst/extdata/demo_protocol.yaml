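name: ecoRI-xhoI-demo
vector: AGCTGCGATTCGACTCCAATCTGCGCGCATCTCGATAGATTGAAGCCATGCTCACGGTTCTGGATCGACTGACAATGTCTAATAGTCCTTTCGTTGCTAACCGAATCTGTAGGAGCTCAGGTTAGTAGCTTCTGGTTTCAATTTTAGCGGAAATCAAGCGCTAGGGGTCCAGTCTTTCTAAGTAACTTTATCCTGAGAAACACAATATATTATCAAATATGTAGACAATTATAACCCTGACTATGTTTCTAGGATATGTTAAGAAGTAATATGTCACGGGCAACGTCGACTTGCTCGACTCATAGGCTCGAATAAACCCATCTACGGTTACATGGTTAATAATAGAGATTCTCTAGGTGCCAGCTTTGTACCCTACGCAATTATCGTTCGAATACAGCCAGGACATTCTTTGTGGTATTAGGCTATGAGGGCCCGTTATTGATAAAGACTTCTGTACAAACTTGAAAGGTTTAAAGCATGCCCCCCTCCATTCAGAGTACGACTTACAGGTCAAAGCGCTACGTTTGTTTACAATAGCATCTGCAATCTTCACGACGCTTGGACTATAGAGTTCGAACGGGCCATGTGGGTCACCCCTCAGTACACCTTACACGAAATCAACGTTAGCTTACCGGACGGATTTTGGCACTACAACGCCATTTCCACTAGTTACGAAGCTTCGCCCACGTCGAATCCATGACCCCAGTGCCTTATACGCCGCATCGGAGTTTGCAACGCTAGGGACAACGATTACATAAGTGGCCTATAACTACAAGTCGAAACTTCCCACAAGGACGCATCATTAATACCCCAGATCTTTGTACGGGTGTACCGCATGCGCATCGATCTGTCACCGATCCACTTTCGAGACAATTACGTGTATCCGATAATTCAGCCTTTACGGAAGCGCCGTCGAGGATTCCGGTAATGAAGCACAGTGCGCATGCATTGTATTGAGAAACCACTTAAATTGCCACCTAGTTGTGTGTTCCGTCCAGGCTCGTATTAGGATCCTTATCCGATACATCATGATTGACATGCTGCGACCCCCCTCAGGTGTTAATGGCTCTAACCTGCTTTGCGATGATAATTTCCCGAGCTACTAGTATGAGATACGCATCGTATCCCTCCTAGGTAATCTCGTTAGATGTCTGGCACCTATGTCCTAGTGCCAGAGTATGCAAGCAGTGTTCCACATTAGAATTCTATGCAGAGCCGTGTATCGATTAAGCGCCCTTGTCACATTAATGCGAACTCAGTTCTAGTGTCAGTTAGGCTACCAGTCCGCTGCCGTGCGCCCCGATTAACTAACTCAGATTACACATTAGACTTTCGACACGGGTAAAACACAAAGTTTGCCGATTATACAGTATCGCTTGGTGCCATTGATACTATAGTTCCGGCAATTTCCTATGATGTGATATCCTCGGGGGCAAATGTGCCCCCGACGCTAAAAATTTTTTTCAACACTTGTCAAAAGTACCCGCTTGTATATATCGCTACGACCTCGAGCGGCAAAGGTGTACCGCTGGAACCTAACCGTGCATTAATACAATGCTTCGACGGAGCAGTTCTCTCCAGGCGAGATGTCACCGGTATAAAAGGCCCACGGTCCAATCTGTGTGCCTAGCCCTCAGGCTCAATCTGTAGCAATCATCTCCCTTTGACGAAATTATACTTCTTTGCAGTAACCCGCAAAATCTCAGTGCTCCGTAATCTCTGCCAGGATGGGAAGACACATATAACCAGAAGTTACGCCTAGCCGCTCCTACCCATCAAGTTATTCTAATGAATGCGTCTCGAAGCTAGCTGCCTCGTAATAACCTATGCTACCGGCGGTTGCTCAAAATCATCACAGCCGGGGCCAGATTTAAAAAACTTTCGTTGTCTTGATCCAGAACCACGGGATGGTATCACTTGATTGCCCCAGCCGGGCTCCAGGGCTCTTGCTAAATGAGGTCAGGCAATCTTCGTTGATATTATTCCTGTAAACAGGGCGTGATAGTTTCTAGATGACTTTTACGACTCCAGGTAGTAATCCGAGGAACATGGGGCGTGAGTATACTCTCCGTGTTGGTCTTAGGCTGAGTCCAGATCGAAAGGACGATATAGACCCACATTTGTTGGTTGCGACGGTGAGTACCTAATGTTAAAAGTCATAGGTCACGTTATGACCTATCTAGATTTGCGCCCTAAATAAAACCCAAGGTGTCGCAGTTCAAAAAATGTACGAATCGTTGCTTGCTTGAGCTTCCATTGTCGTTGAGGTCCCGTTTGTGTATTTTTGGACAAGAAATAAAGTATATCTCCTTCGCATCGTGAACCTTACCTACTACGTCGGATTCGAACAGGTCCTGAGGTTTTAGACACCGGGCCTGTCGTGAGAGATCTCGTAAGTGTTACAGAAGTGGTATGTTTGCAGTTCGTGTACCAACCTATCAATGGTTGAGCATAGCTAGGAGCGTCTAGAGTCAGGTCGATGAAGGCCATTTTCGAGTCCATTACAAAGCGTAATTCAGTGTGAGGTGTCTCAAAGGGGCTGAGCACGGCTCCACAAGAAAATATCATGTCTGTGTCACGCATGAAGACTACGGGTTTTATTTCGCCCGCTCACGATTCTTTTTAGGACGCCGATTGTTACAATAGTCTCGCGTTAGTCTGTTTTTAGACCGACTCAAATTATCAAAGCATTAAATGGGTTATAAAATGTAT
vf1:
- 1151
- 1200
vf2:
- 1513
- 1562
enzyme1: GAATTC
enzyme2: CTCGAG
adapter_sense: GGCACGAGG
adapter_antisense: CCTCGTGCC
direction_rules:
- pattern: \.g1
  direction: 5'
- pattern: \.b1
  direction: 3'
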