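>b4_2
GGAGCGCCCTACGGGACGCGCCCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTGTCCGGAAAAAACTTTGAAGATTCTTGAAGAGTCTGTCCAGTGCGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAAGGAC
>b4_1
GGAGCGCCCTACGGGACGCGCCCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTGTCCGGAAAAAACTTTGAAGATTCTTGAAGAGTCTGTCCAGTGCGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAAGGAC
>b1_2
GGAGCGCCCTACGGGGCGCGCCCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTGTCCGGAACAAACTTTGAAGATTCTTGAAGAATCTGTCCAGTGCGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAAGGAC
>b1_1
GGAGCGCCCTACGGGGCGCGCCCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTGTCCGGAACAAACTTTGAAGATTCTTGAAGAATCTGTCCAGTGCGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAAGGAC
>b2_2
GGAGCGCCCTACGGGGCGCGCCCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTGTCCGGAACAAACTTTGAAGATTCTTGAAGAATCTGTCCAGTGAGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAAGGAC
>b2_1
GGAGCGCCCTACGGGGCGCGCCCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTGTCCGGAACAAACTTTGAAGATTCTTGAAGAATCTGTCCAGTGAGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAAGGAC
>b3_2
GGAGCGCCCTACGGGGCGCGACCGCCCCGTCCAAAATCGAGCGACCGAGGTTGGTAAGTACCTGTGTCCGGAACAAACTTTGAAGATTCTTGAAGAATCTGTCCAGTGCGTTGCTAATAAGATTACTGGCGTTATGGATTTGTTAAGGAC
>b3_1
GGAGCGCCCTACGGGGCGCTACCGCCCCGTCCAAAATCGAGCGACCGAGGTTGGTAAGTACCTGTGTCCGGAACAAACTTTGAAGATTCTTGAAGAATCTGTCCAGTGCGTTGCTAATAAGATTACTGGCGTTATGGATTTGTTAAGGAC
>a3_2
GGAGCGCCCTACGGGACACGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTCAGTACCTGTTTCCGGAAAAACCTTTGACGATTCTTGAAGAGTCTGCCCAGTGCGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAATGAC
>a3_1
GGAGCGCCCTACGGGACACGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTCAGTACCTGTTTCCGGAAAAACCTTTGACGATTCTTGAAGAGTCTGCCCAGTGCGTTGATAATAAGATTGCTGCCGTTATGGATTTGTTAATGAC
>a1_1
GGAGCGCCCTACGGGACGCGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTTTCCGGAGAAAACTTTGAAGATTCTTGAAGAGTCTGCACAGTGCGTTGATAATAAGATTACTGCCGTTTTGGATTTGTTAATGAC
>a1_2
GGAGCGCCCTACGGGACGCGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTTTCCGGAGAAAACTTTGAAGATTCTTGAAGAGTCTGCACAGTGCGTTGATAATAAGATTACTGCCGTTTTGGATTTGTTAATGAC
>a2_2
GGAGCGCCCTACGGGACGCGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTTTCCGGAAAAAACTTTGAAGATTCTTGAAGAGTCTGCACAGTGCGTTGATAATAAGATTACTGCCGTTTTGGATTTGTTAATGAC
>a2_1
GGAGCGCCCTACGGGACGCGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGGTAAGTACCTGTTTCCGGAAAAAACTTTGAAGATTCTTGAAGAGTCTGCACAGTGCGTTGATAATAAGATTACTGCCGTTTTGGATTTGTTAATGAC
>a4_2
GGAGCGCCCTACGGGACGCGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGATAAGTACCTGTTTCCGGAAAAAACTTTGAAGATTCTTGAAGAGTCTGCCCAGTGGGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAATGAC
>a4_1
GGAGCGCCCTACGGGACGCGCTCGCCCCGTCCCAAATCGAGCGACCGAGGTAGATAAGTACCTGTTTCCGGAAAAAACTTTGAAGATTCTTGAAGAGTCTGCCCAGTGGGTTGATAATAAGATTACTGCCGTTATGGATTTGTTAATGAC
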