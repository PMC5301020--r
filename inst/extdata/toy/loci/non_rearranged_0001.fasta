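>b3_2
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTAGCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGAACGA
>b3_1
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGAACGA
>b2_2
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGATAATTCTTGCGTTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGGACGA
>b2_1
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGATAATTCTTGCGTTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGGACGA
>b1_2
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGCTAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGGACGA
>b1_1
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGCTAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGGACGA
>b4_2
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGATAGGACGA
>b4_1
CTGGGCTTTCTAGCGGTGTCTTGGAAGGTGTGAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGATAGGACGA
>a2_1
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTGAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGAACGA
>a2_2
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTGAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGAACGA
>a3_2
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTAAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGAAGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGAACGA
>a3_1
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTAAGGGATAATTCTTGCGGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGAAGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGTAGAACGA
>a1_2
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTGAGGGATAATTCTTGCTGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGGCAATATCGAGCGCTCTCGGTAGAACGA
>a1_1
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTGAGGGATAATTCTTGCTGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGGCAATATCGAGCGCTCTCGGTAGAACGA
>a4_1
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTGAGGGATAATTCTTGCTGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGGCAATATCGAGCGCTCTCGGTAGAACGA
>a4_2
CTGGGCTTTCTAGCGATGTCTTGGAGGGTGTGAGGGATAATTCTTGCTGTACATATCGTGGACAGGAGTCACTACCCAGGCGGAGCCTAGATGCTCCGGGAGCATGGACGCATTTGAGTGGGCCAATATCGAGCGCTCTTGGCAGAACGA
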