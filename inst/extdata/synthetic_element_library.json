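{
  "elements": [
    {
      "index": 1,
      "name": "e01",
      "consensus": "GTAGCGGGGGTGCGTGACGATGTGTCACGACACATGACATCAACCGTCATGGGGTCCGAGGGGAATGTGATAGGGGTATATGTGAGACCGACAACTCAAGTGCTCTACCCGAAG",
      "min_len": 114,
      "max_len": 114
    },
    {
      "index": 2,
      "name": "e02",
      "consensus": "GTGAACCGCCTCCCAGACCGGGCAGTCATGAACCCCCTACCATCGTCAGGGAATGGGCTCAGGGACGAGCATCTTAGCTTTGTCCATGGAACAGAGCGTGACAGACGATGTAACCGT",
      "min_len": 117,
      "max_len": 117
    },
    {
      "index": 3,
      "name": "e03",
      "consensus": "TTGGCGTTTCAGATAAGACATCATGGCTCCACAGGTCAGTGGATTATCGTTGTCAGTCTTCTGAGTCGGCGAATAATGGCTGCCCAAGCTGTTAATATAAACGCGAGTATCTTCGTCAAGAGTATCCGAAATAGT",
      "min_len": 135,
      "max_len": 135
    },
    {
      "index": 4,
      "name": "e04",
      "consensus": "GAGCCAGATGCCGAAACGTGTAGGGGGTCCCACTTTTCCTTAAGCATGTACACAGAGCAGTTTGGAGCTCGAGTGATGAGTGTTACGATTGACTCAAGGATTGATGTA",
      "min_len": 108,
      "max_len": 108
    },
    {
      "index": 5,
      "name": "e05",
      "consensus": "TGGCTCCGGGGGACTATAGCATACTACCCTACTTTTTGCATTGATGTTACGAGGCCCAGACGATCGCTTCCTGAGCACACGTCAACGTTTGTTGCAGCGGAGATACTACCGGCTCATAGAGCATCACACACTCGGCAACGATGGCAC",
      "min_len": 147,
      "max_len": 147
    },
    {
      "index": 6,
      "name": "e06",
      "consensus": "TTGGATAACGTATGGTCATCTATAGCCTACCTGTCGCATTCCGGAGTATCGTCTCAATGTGCCCAAAAAAGAAGCTCTCGCTATCAGAACCTACCAAACAGGATACACGTGCACTATCTCTTGATGGATTTCTGCGTCATT",
      "min_len": 141,
      "max_len": 141
    },
    {
      "index": 7,
      "name": "e07",
      "consensus": "TCATTCTGCATGAACTTGATAGCAAGAACCGGGCCAAACGATCAACTAAGCAGGGACTTTATGAGCGCCCTGGTTCCGGCCCTTTTAGCAGGGGTTTTATCCGTTTCGAGTGGACCGTCTGCG",
      "min_len": 123,
      "max_len": 123
    },
    {
      "index": 8,
      "name": "e08",
      "consensus": "GCCTCCGTCCGGACACTAGCCTACGAAACATACGTAGAGATGTCTTCCGGTAATGACTTTAACTCTGTTGACCCCCAATCAGTTCGCGGAGAGGGCTTAACTCTT",
      "min_len": 105,
      "max_len": 105
    },
    {
      "index": 9,
      "name": "e09",
      "consensus": "TGTTCTAAGGAATTTCGGACACGCGCCGTCGTGGACTACGTATGTGATCCTGCCGACGGCTTGGTCCTTATCATTAAGAACTTATATATAGATCCTAGTGTGCAGGGG",
      "min_len": 108,
      "max_len": 108
    },
    {
      "index": 10,
      "name": "e10",
      "consensus": "AAGGGTTACGACGTGGGTGATAGAACATCGGAATATCGATCTACGGTACATAAGCCTTGGATAAGAAATCACTCTGTGTCGCCAACTAATCAGCCGTTCGGCGCCCCAAGCCCATTA",
      "min_len": 117,
      "max_len": 117
    }
  ],
  "patterns": {
    "A3": ["e01", "e02", "e03", "e06", "e08", "e09", "e10"],
    "C2": ["e01", "e02", "e03", "e05", "e06", "e08", "e09", "e10"],
    "D1": ["e01", "e02", "e05", "e06", "e09", "e10"],
    "C3": ["e01", "e02", "e03", "e04", "e05", "e06", "e07", "e08", "e10"],
    "D5": ["e01", "e02", "e03", "e04", "e06", "e07", "e08", "e10"],
    "B3": ["e01", "e03", "e04", "e05", "e07", "e08", "e09", "e10"],
    "E2": ["e01", "e02", "e07", "e10"],
    "01": ["e01", "e02", "e03", "e04", "e05", "e06", "e07", "e10"],
    "02": ["e01", "e02", "e03", "e05", "e06", "e07", "e08", "e09", "e10"],
    "G1": ["e01", "e04", "e06", "e08", "e09", "e10"],
    "B8": ["e01", "e02", "e05", "e06", "e08", "e09", "e10"],
    "D2": ["e01", "e02", "e03", "e04", "e05", "e06", "e07", "e08", "e09", "e10"]
  }
}
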