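{
  "name": "example-early-scheme (synthetic demonstration, not a published design)",
  "alphabet": ["A", "D", "E", "G", "I", "L", "P", "S", "T", "V"],
  "positions": [
    {
      "position": 1,
      "wild_type": "S",
      "allowed": ["A", "G", "S", "T"],
      "fixed": false,
      "codon": "RSC"
    },
    {
      "position": 2,
      "wild_type": "D",
      "allowed": ["D", "E", "G"],
      "fixed": false,
      "codon": "GRK"
    },
    {
      "position": 3,
      "wild_type": "E",
      "allowed": ["D", "E", "V"],
      "fixed": false,
      "codon": "GWK"
    },
    {
      "position": 4,
      "wild_type": "V",
      "allowed": ["A", "I", "L", "V"],
      "fixed": false,
      "codon": "DYA"
    },
    {
      "position": 5,
      "wild_type": "E",
      "allowed": ["A", "D", "E"],
      "fixed": false,
      "codon": "GMK"
    },
    {
      "position": 6,
      "wild_type": "V",
      "allowed": ["G", "L", "V"],
      "fixed": false,
      "codon": "KKG"
    }
  ]
}
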