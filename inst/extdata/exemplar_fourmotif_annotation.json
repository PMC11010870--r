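{
  "seed": 1,
  "perturbation": {
    "node": "P",
    "type": "ON"
  },
  "motifs": {
    "yellow": ["Y1", "Y2"],
    "green": ["G1", "G2"],
    "purple": ["U1", "U2"],
    "blue": ["B1", "B2"]
  },
  "interconnectors": "I1",
  "markers": [1, -1],
  "optimal_pair": {
    "node": "I1",
    "type": "OFF"
  }
}
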