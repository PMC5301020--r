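>a4_1
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTAGGTAGCGATGTCCCCTCCAGCCGGGAGAAGTACGCAGCCAGTTGCAGTGCGGTGTCCAGCTTAGTGTTTACGATATGGAGACTACAGACACCTAGCTACTCACTACTG
>a4_2
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTAGGTAGCGATGTCCCCTCCAGCCGGGAGAAGTACGCAGCCAGTTGCAGTGCGGTGTCCAGCTTAGTGTTTACGATATGGAGACTACAGACACCTAGCTACTCACTACTG
>a2_2
TCTCGCGGTCGTGTAGGCTATTTAACCGTGTTAGTTCCCGTAGGTGGCGATGTCCCCTCCAACCGGGAGAAGTACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTAGTGTTTGCGATATGGAGACAACAGACACGTAGCTGCTCACTACTG
>a2_1
TCTCGCGGTCGTGTAGGCTATTTAACCGTGTTAGTTCCCGTAGGTGGCGATGTCCCCTCCAACCGGGAGAAGTACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTAGTGTTTGCGATATGGAGACAACAGACACGTAGCTGCTCACTACTG
>a1_2
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTAGGTGGCGATGTGCCCTCCAACCGGGAGAAGTACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTTGTGTTTGCGATATGGAGACAACAGACACGTAGCTACTCACTACTG
>a1_1
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTAGGTGGCGATGTCCCCTCCAACCGGGAGAAGTACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTAGTGTTTGCGATATGGAGACTACAGACACCTAGCTACTCACTACTG
>a3_2
TCTGGCGTTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTAGGTGGCGATGTCCCCTCCAACCGGGAGAAGTACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTAGTGTTTGCGATATGGAGACTACAGACACCTAGCTACTCACTACTG
>a3_1
TCTGGCGTTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTAGGTGGCGATGTCCCCTCCAACCGGGAGAAGTACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTAGTGTTTGCGATATGGAGACTACAGACACCTAGCTACTCACTACTG
>b1_2
TCTCGCGTTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTCCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTGGGGTGTCCAACTTAGTGTTTGCGATAAGGAGACTCCAGACACCTAGCTACTCACTACTG
>b1_1
TCTCGCGTTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTCCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTGGGGTGTCCAACTTAGTGTTTGCGATAAGGAGACTCCAGACACCTAGCTACTCACTACTG
>b3_1
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTCCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTGGGGTGTCCAACTTAGTGTTTGCGATAAGGAGACTACAGACACCTAGCTACCCACTACTG
>b3_2
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTCCTCCAACCGGGAGAAAGACGCAGCCAGTTGCAGTGGGGTGTCCAACTTAGTGTTTGCGATAAGGAGACTACAGACACCTAGCTACCCACTACTG
>b2_1
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTGCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTGGGGTATCCAGCTTAGTGTTTGCGATATGGAGACTACAGACACCTTGCTACTCACTACTG
>b2_2
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTGCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTGGGGTGTCCAGCTTAGTGTTTGCGATATGGAGACTACAGACACCTAGCTACTCACTACTG
>b4_2
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTCCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTCGGGTGTCCAGCTTAGTGTATGCGATATGGAGACTACAGACACCTAGCTACTCACAACTG
>b4_1
TCTCGCGGTCGTGTAGGCTATTTAACCATGTTAGTTCCCGTACGTGACGATGTCTCCTCCAACCGGGAGAAATACGCAGCCAGTTGCAGTCGGGTGTCCAGCTTAGTGTATGCGATATGGAGACTACAGACACCTAGCTACTCACAACTG
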