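>b3_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTACAAGCCCGGACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTTCTATTGTGACTGATGTGCGATTGGTCCGGGCAGAAAGTTTATCGGCAAT
>b4_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTACAAGCCCGTACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTCCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>b4_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTACAAGCCCGTACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTCCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>b2_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTACAAGCCCGGACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTTCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTGATCGGCAAT
>b2_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTACAAGCCCGGACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTTCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTGATCGGCATT
>b1_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGCGATTACCCAGATCTACAAGCCCGGACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTTCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTGATCGGCAAT
>b1_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGCGATTACCCAGAACTACAAGCCCGGACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTTCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTGATCGGCAAT
>b3_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTACAAGCCCGGACCCGATGTTATGTTTTTTTCTATTCGAATGGCCATCTTCTATAGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a1_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGTACCCGATGTTATGTTTTTTTCTTTTCGAATGGCCATCTTCTATTGTGACTGATGTGCGATTGCTCCCGGCAGAAAGTTTATCGGCAAT
>a4_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGTACCCGATGTTATGTTTTTTTCTTTTCGAATGGCCATCTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a3_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGGACCCGAAGTTATGTTTTTTTCTTTTCGAATGACCATCTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a3_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGGACCCGAAGTTATGTTTTTTTCTTTTCGAATGACCATCTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a2_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGGACCCGATGTTATGTTTTTTTCTTTTCGAATGGCCATCTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a2_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGGACCCGATGTTATGTTTTTTTCTTTTCGAATGGCCATCTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a1_1
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGGACCCGATGTTATGTTTTTTTCTTTTCGAATGGCCAACTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
>a4_2
TTATCGCGAGAAAACGCCGGATTCTCGTACGACTTTGTGATTACCCAGAACTAGAAACCCGGACCCGATGTTATGTTTTTTTCTTTTCGAATGGCCAACTTCTATTGTGACTGATGTGCGATTGGTCCCGGCAGAAAGTTTATCGGCAAT
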