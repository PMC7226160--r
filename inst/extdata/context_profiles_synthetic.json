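{
  "trmFO": {
    "window": 5,
    "sets": [
      ["mnmG", "rsmG", "jag", "spoIIIJ", "rnpA", "parB"],
      ["mnmG", "rsmG", "jag", "spoIIIJ", "rnpA", "dnaA"]
    ]
  },
  "rlmFO": {
    "window": 5,
    "sets": [
      ["rpsB", "tsf", "pyrH", "frr", "uppS", "cdsA"],
      ["rpsB", "tsf", "pyrH", "frr", "uppS", "dnaJ"]
    ]
  },
  "trmFO_like": {
    "window": 5,
    "sets": [
      ["folT", "ecfA", "ecfT", "glpK", "ldh"]
    ]
  }
}
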