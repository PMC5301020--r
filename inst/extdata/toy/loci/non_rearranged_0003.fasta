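>a4_2
CATTGTACCCGTTTTCATAGTAGCATAAGCGAATGTATTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCAAAGCCGAACGAAACTGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>a1_2
CATTGTACCCGTTTTCATAGTAGCATAAGCGAATGTATTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCAAAGCCGAACGAAACTGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>a1_1
CATTGTACCCGTTTTCATAGTAGCATAAGCGAATGTATTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCAAAGCCGAACGAAACTGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>a4_1
CATTGTACCCGTTTTCATAGTAGCATAAGCGAATGTATTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCAAAGCCGAACGAAACTGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCCTGCTATAC
>a2_2
CATTGCACCCGTTTTCATAGTAGCATAAGCAAATGTGTTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCATAGCCGAACGAAACCGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>a2_1
CATTGCACCCGTTTTCATAGTAGCATAAGCAAATGTGTTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCATAGCCGAACGAAACCGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>a3_2
CATTGCACCCGTTTTCATAGTAGCATAAGCAAATGTGTTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCATAGCCTAACGAAACTGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>a3_1
CATTGCACCCGTTTTCATAGTAGCATAAGCAAATGTGTTGTGGCTCCGCATATCCATCGGTCGCACGGGCTATCCTACGCTCCGCATAGCCTAACGAAACTGACTGGGTGGGATACTCGCTCTGCACACCGATGTCCGGGCTTGCTATAC
>b1_2
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCGGCATATCCATCGGACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b1_1
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCGGCATATCCATCGGACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b2_1
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCGGCATATCCAGCGGACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b2_2
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCGGCATATCCAGCGGACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b4_1
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCCGCATATCCATCGTACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b4_2
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCCGCATATCCATCGTACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b3_2
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCCGCATATCTATCGGACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
>b3_1
CATTGCACCTGTTTTCATAGTAGCATAAGCCAATGTGTTGTGGCTCCGCATATCCATCGGACGCACAGGCTATCCTACGCTCCGCATAGCCGAACGAAACTGACTGGGTGGGATAGTCGCTCTGCACACCGACGTCCGGGCTTGCTCTAC
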