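>a4_2
CGGGTCGTTAGCCCAGATTGAAATGAGGAAGTGGTGCAGTAGTTCGGTGTACCAAAGGCGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAATCACTTTCTACAAACTCTAGC
>a4_1
CGGGTCGTTAGCCCAGATTGAAATGAGGAAGTGGTGCAGTAGTTCGGTGTACCAAAGGCGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAATCACTTTCTACAAACTCTAGC
>a3_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGTTCGGTGTTCCAGAGGCGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAAGCACTTTCTACAAACTCTAGC
>a3_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGTTCGGTGTTCCAGAGGCGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAAGCACTTTCTACAAACTCTAGC
>a2_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGTTCGGTGTACCAGAGGAGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAAGCACTTTCTACAAACTCTAGC
>a2_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGTTCGGTGTACCAGAGGAGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAAGCACTTTCTACAAACTCTAGC
>a1_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGTTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAAGCACTTTCTACAAACTCTAGC
>a1_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGTTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCTCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGGACTGCTAAGCACTTTCTACAAACTCTAGC
>b1_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCAAAGCACTTTCAACAAACTCTAGC
>b1_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCAAAGCACTTTCAACAAACTCTAGC
>b2_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCAAAGCACTTTCAACAAACTCTAGC
>b2_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCAAAGCACTTTCAACAATCTCTAGC
>b3_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCTAAGCACTTTCAACAAACTCTAGC
>b3_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCTAAGCACTTTCAACAAACTCTAGC
>b4_1
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCTAAGCACTTTCAACAAACTCTAGC
>b4_2
CGGGTCGTTAGCCCAGATTGAAAAGAGGAAGTGGTGCAGTAGCTCGGTGTACCAGAGGCGCTTTCGGGACCGGTGGCGCTATTTGTCCGAAGCGCGATATATTGTGCATGGAACTGCTTGCACTGCTAAGCACTTTCAACAAACTCTAGC
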