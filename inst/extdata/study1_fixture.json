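{
  "n": {"control": 416, "national": 125, "international": 67},
  "source": "empirical",
  "enrichment": true,
  "effects": {
    "baseline": 199.65,
    "sd": 27,
    "shifts": {
      "rs1815739": {"TT": -8.77},
      "rs41274853": {"CC": -11.68}
    }
  }
}
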