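>a1_2
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACTCCCATCAAAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTTACACAGTTCAGGTGATAATATGGCCAAACACC
>a1_1
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACTCCCATCAAAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTTACACAGTTCAGGTGATAATATGGCCAAACACC
>a2_1
CCAGCCCCGCTAGTGGCCCGCCAGAGGACGACAATTCCGACTCCCATCAAAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATAGTTACAGTGGGTAGTCCGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>a2_2
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACTCCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>a3_2
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACTCCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>a3_1
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACTCCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>a4_2
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTAACACAGTTCAAGTCATAATATGGCCAAACACC
>a4_1
CCAGCCCAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTTAGAGTATATTTACAGTGGGTAGTCCGTTCATAGTAACACAGTTCAAGTGATAATATGGCCAAACACC
>b3_1
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGCCACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>b3_2
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGCCACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>b1_2
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACACCCACCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>b1_1
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACACCCACCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>b2_1
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>b2_2
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGACACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATATGGCCAAACACC
>b4_1
CCAGCCTAGCTAGGGGCCCGCCAGAGGACGACAATTCCGCCACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTACGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAAGTGATAATTTCGCCAAACACC
>b4_2
CCAGCCTAGCTAGTGGCCCGCCAGAGGACGACAATTCCGCCACCCATCATAGATCTTCCCCACTCTATCTGTCCTTTAGGTTGAGAGTATATTTACAGTGGGTAGTACGTTCATAGTTACACAGTTCAACTGATAATATGGCCAAACACC
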