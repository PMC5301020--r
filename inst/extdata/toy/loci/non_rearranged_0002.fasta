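>b4_2
AAGGCGACCGACCTTGACTAAATGGAGCGACTACTAAGGCCGCAAACGCATTTCGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>b4_1
AAGGCGACCGACCTTGACTAAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>b3_2
AAGGCGACCGACCTTGACTTAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCGACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGAGAGTCCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>b3_1
AAGGCGACCGACCTTGACTTAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCGACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGAGAGTCCGCCTATTGCCGCGTCTAATACCCTCCCGTTTTTAGCCGGGCAT
>b2_2
AAGGCGACCGACCTTGAATTAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>b2_1
AAGGCGACCGACCTTGAATTAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>b1_2
AAGGCGACCGACCTTGAATTAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCCACGTGAAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>b1_1
AAGGCGACCGACCTTGAATTAATGGAGCGACTACTAAGGCCGCAAACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTAATACCCTCCCGCTTTTAGCCGGGCAT
>a1_2
AAGGCGACCGACCTTGACATAATGGAGCGACTACTAAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGCTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a4_1
AAGGCGACCGACCTTGACATAATGGAGCGACTACTAAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGCTCGCCTATTGCTGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a4_2
CAGGCGACCGACCTTGACATAATGGAGCGACTACTAAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGCTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a1_1
CAGGCGACCGACCTTGACATAATGGAGCGACTACTAAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGCTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a3_1
AAGGCGACCGACCTTGACATAATGGAGCGACTACTAAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a3_2
AAGGCGACCGACCTTGACATAATGGAGCGACTACTAAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a2_1
AAGGCGACCGACCTTGACATAATGGAGCGACTACTCAGGCCGCATACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCGCGTAAGGGAGTTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
>a2_2
AAGGCGACCGACCTTGACATAATGGAGCGACTACTCAGGCCGCTTACGCATTTAGCCACGTGGAGGTCTCTTCTCCCTTCCGTAGTTGAATGCTCGTAAGGGAGTTCGCCTATTGCCGCGTCTTATATCCTCCCGCTTTTAGCCGGGGAT
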