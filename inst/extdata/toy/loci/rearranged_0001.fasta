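>a3_2
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGAAGTGCACGAGCGCAGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGTA
>a3_1
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGAAGTGCACGAGCGCAGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGTA
>a2_2
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAACTAACTCCGGCTGAGACTGTCCTGGTAGAAGTGTACGAGCGCAGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGTA
>a2_1
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGAAGTGCACGAGCGGAGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACCGGTGGGCTTTGCCTCCAAATAGTA
>a1_2
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGAAGTGGACGAGCGCAGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGTA
>a1_1
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGAAGTGGACGAGCGCAGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGTA
>a4_2
CGACCGTATTCAACCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGTTGAGACTGTCCTAGTAGACGTGCACGAGCGCAGCAGTCTCATGTGTACGGTTTTAAATCGTAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATACCA
>a4_1
CGACCGTATTCAGCCAAAGTCGTGAACCTTAACTAGAAATAACTCCGGTTGAGACTGTCCTAGTAGACGTGCACGAGCGCAGCAGTCTCTTGTGTACGGTTTTTAATCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCTAATACCA
>b4_2
CGACCGTATTCAACCAAAGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGACGTGCACGAGCGCGGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b4_1
CGACCGTATTCAACCAAAGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGACGTGCACGAGCGCGGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b3_1
CTACCGCATTCAACCAAAGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGACGTGCACGAGCGCGGCAGTCTCATATGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b3_2
CGACCGCATTCAACCAAAGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGACGTGCACGAGCGCGGCAGTCTCATATGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b1_1
CAACCGCATTCAACCAACGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGAAGACGTGCACGAGCGCGGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b1_2
CAACCGCATTCAACCAACGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGAAGACGTGCACGAGCGCGGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b2_2
CGACCGCATTCAACCAAAGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTACACGTGCACGAGCGCGGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
>b2_1
CGACCGCATTCAACCAAAGTCTTGAACCTTAACTAGAAATAACTCCGGCTGAGACTGTCCTGGTAGACGTGCACGAGCGCGGCAGTCTCATGTGTACGGTTTTAAACCGCAAGACACGCGCCTACTGGTGGGCTTTGCCTCCAAATAGCA
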