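{
  "seed": 42,
  "n_individuals": 2,
  "loci_per_class": {
    "X": 4,
    "rearranged": 4,
    "non_rearranged": 4
  },
  "locus_length": {
    "X": 150,
    "rearranged": 150,
    "non_rearranged": 150
  },
  "mu": 0.004,
  "ne_scale": {
    "X": 0.75,
    "rearranged": 1,
    "non_rearranged": 1
  },
  "species_tree": "((((a1:1,a2:1):1,a3:2):1,a4:3):3,(((b1:1,b2:1):1,b3:2):1,b4:3):3);",
  "introgression": [
    {
      "donor": "a4",
      "recipient": "a1",
      "time": 0.1,
      "p_X": 0,
      "p_rearranged": 0,
      "p_non_rearranged": 0.8
    }
  ]
}
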