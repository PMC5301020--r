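>a2_1
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGCTGGTGGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a2_2
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGCTGGTGGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a1_1
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGCTTGTGGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a1_2
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGCTTGTGGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a3_1
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGATTGTGGGCTCGACCCCTCGCACCTACCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a3_2
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGATTGTGGGCTCGACCCCTCGCACCTACCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a4_1
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGCTTGTGGGCTTGACCCCTCGCGCCTTCCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>a4_2
CCTTATCCTTGGCATGCTTTTGCGAGCACGGAGCTGGCGAGGCAGGGCATAGTAATTAGACATCTAGTTCATACGCTTGTGGGCTTGACCCCTCGCGCCTTCCGAGGGATGAGGGTGCACTTCGCTGAAACGAGAGTCCGTATTGTGAGG
>b1_2
CATTATCCTTGGCATGCTTTTGCGAGTACGGAGCTTGCGAGGCAGGGCATAGTAATTAGAGATCTAGTTCATACGGTTGTCGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTACTTCGCTGAAACCAGAGTCCGAATTGTGAGG
>b2_1
CCTTATCCTTGGCATGCTTTTGCGAGTACGGAGCTTGCGAGGCAGGGCATAGAAATTAGAGATCTAGTTCATACGGTTGTCGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTACTTCGCTGAAACCAGAGTCCGAATTGTGAGG
>b2_2
CCTTATCCTTGGCATGCTTTTGCGAGTACGGAGCTTGCGAGGCAGGGCATAGTAATTAGAGATCTAGTTCATACGGTTGTCGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTACTTCGCTGAAACCAGAGACCGAATTGTGAGG
>b1_1
CCTTATCCTTGGCATGCTTTTGCGAGTACGGAGCTTGCGAGGCAGGGCATAGTAATTAGAGATCTAGCTCATACGGTTGACGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTACTTCGCTGAAACCAGAGTCCGAATTGTGAGG
>b4_2
CCTTATCCTTGGCATGCTTTTGCGAGTACGGAGCATGCGAGGCAGGGCATAGTAATTAGAGATCTAGTTCATACGCTTGTCGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTGCTTCGCTGAAACCAGAGTCCGAATTGTGAGG
>b4_1
CCTTATCCTTGGCATGCTTTTGCGAGTACGGAGCATGCGAGGCAGGGCATAGTAATTAGAGATCTAGTTCATACGCTTGTCGTCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTGCTTCGCTGAAACCAGAGTCCGAATTGTGAGG
>b3_1
CCTTATCCTTAGCATGCTTTTGCGAGAACGGAGCTTGCGAGGCAGGGCATAGTAATTAGAGATCTAGTTCATACGCTTGTCGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTACTTCGCTGAAACCAGAGTCCGAATTGTGAGG
>b3_2
CCTTATCCTTGGCATGCTTTTGCGAGAACGGAGCTTGCGAGGCAGGGCATAGTAATTAGAGATCTAGTTCATACGCTTGTCGGCTTGACCCCTCGCACCTACCGAGGGATGAGGGTGTACTTCGCTGAAACCAGAGTCCGAATTGTGAGG
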