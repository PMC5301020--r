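>a3_1
GTATTGAGAGCCGTGGGGACTGTAGAGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAACCCGGACCATGTTGATAGAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a3_2
GTATTGAGAGCCGTGGGGACTGTAGAGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAACCCGGACCATGTTGATAGAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a4_1
GTATTGAGAGCCGTGGGGACTGTAGAGTCGTCCTGCTTCATTTAAAGTCGGCGTTATTCATTCATAGCCCGGACCATGTTGATAGAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a4_2
GTATTGAGAGCCGTAGGGACTGTAGAGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAGCCCGGACCATGTTGATAGAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a1_1
GTATTGAGAGCCGTCGGGACTGTAGTGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAACCCGGACCATGTTGATACAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a1_2
GTATTGAGAGCCGTCGGGACTGTAGTGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAACCCGGACCATGTTGATACAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a2_1
GTATTGAGAGCCGTCGGGACTGTAGAGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAACCCGGACCATGTTGATAGAAGAGCATTAAGACAACAAGCGCGTACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>a2_2
GTATTGAGAGCCGTCGGGACTGTAGAGTCGTCCTGCTTCATTTAAAGTCTGCGTTATTCATTCATAACCCGGACCATGTTGATAGAAGAGCATTAAGACAACAAGCGCGGACCCAACACAACAGGTTCTCTCTGCACCGTGAAGTCGACC
>b3_1
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCTGCGTTATTCATTCAAAACCCGGACCGTGTTGATAGAACAGCATTGAGACAACAAGCGCGAAGCCAACACAACTGGTTCTCTCTGCACCGTGAAGTCGACC
>b3_2
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCTGCGTTATTCATTCAGAACCCGGACCGTGTTGATAGAACAGCATTGAGACAACAAGCGCGAAGCCAACACAACTGGATCTCTCTGCACCGTGAAGTCGACC
>b2_1
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCTGCGTTATTCATTCAGAACCCGGACCGTGTTGATAGAACAGCATTGAGACAACAAGTGCGAAGCCAACACAACTGGTTCTCTCTGCACCGTGAAGTCGACC
>b2_2
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCTGCGTTATTCATTCAGAACCCGGACCGTGTTGATAGAACAGCATTGAGACAACAAGTGCGAAACCAACACAACTGGTTCTCTCTGCACCGTGAAGTCGACC
>b1_1
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCTGCGTTATTCATTCAGAACCCGGACCGTGTTGATAGAACAGCATTCAGACAACAAGCGCGAAGCCAACACAACTGGTTCTCTCTGCACCGTGAAGTCGACC
>b1_2
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCTGCGTTATTCATTCAGAACCCGGACCGTGTTGATAGAACAGCATTCAGACAACAAGCGCGAAGCCAACACAACTGGTTCTCTCTGCACCGTGAAGTCGACC
>b4_1
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCCGCGTTATTCATTCAGAACCCGGACCGTGTTGATAGAAGAGGATTAAGACAACCAGCGCGTATCCAACACACCTGGTTCTCTCTGCACCGTGAAGTCGACC
>b4_2
GTATTGAGAGCCGTCGGGACTGTATAGTCGTCATGCTTCATTTAAAGTCCGCGTTATTCATTCAGAACCCGGACCGTGTAGATAGAAGAGGATTAAGACAACCAGCGCGTACCCAACACAACTGGTTCTCTCTGCACCGTGAAGTCGACC
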