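>a4_1
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCGCTGTCGACTGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>a4_2
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAGATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCGCTGTCGACTGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>a1_1
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATTCATACGGCGCTAAGCTGGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCGCTGTCGACTGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>a1_2
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGCATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCGCTGTCGACTGGGTGAACGAGTCTCGTACGCGGGATGTGTAT
>a2_2
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGCATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCCCTGTCGACTGGGTGAACGAGTCTCGTACGCGGGATGTGTAT
>a2_1
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGCATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCCCAAATTGCAACAACCATAGGCACTGGGCCGCTGTCGACTGGGTGAACGAGTCTCGTACGCGGGATGTGTAT
>a3_2
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGCATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCACTGTCGACTGGGTGAACGAGTCTCGTACGCGGGATGTGTAT
>a3_1
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGCATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCGTCCACAAATTGCAACAACCATAGGCACTGGGCCACTGTCGACTGGGTGAACGAGTCTCGTACGCGGGATGTGTAT
>b4_2
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATCCACAAATCGCAACAACCATAGGCACAGGGCCGCTGTCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b4_1
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATCCACAAATCGCAACAACCATAGGCACAGGGCCGCTGTCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b3_1
GAGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATCCACAAATCGCAACAACCATAGGCACAGGGCCGCTGCCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b3_2
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATCCACAAATCGCAACAACCATAGGCACAGGGCCGCTGCCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b2_1
GGGACATAAGCGTAAGTACTCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATCCACAAATCGCAACAACCATAGGCACAGGGCCGCTGTCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b2_2
GGGACATAAGCGTAAGTACTCAAGCGTGGCTCCAAATGTATACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATCCACAAATCGCAACAACCATAGGCACAGGGCCGCTGTCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b1_2
GGCACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTTTACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATTCACAAATCGCAACAACCATAGGCACAGGGCCGCTGTCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
>b1_1
GGGACATAAGCGTAAGTACGCAAGCGTGGCTCCAAATGTTTACGGCGCTAAGCTTGGGTATACTAGTGCGGACCATTCACAAATCGCAACAACCATAGGCACAGGGCCGCTGTCGACAGGGTGACCGAGTCTCGTACGCGGGATGTGTAT
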