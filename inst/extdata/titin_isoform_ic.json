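{
  "isoform": "IC",
  "total_residues": 35991,
  "regions": {
    "label": ["Z-disk", "I-band", "I/A junction", "A-band", "M-band"],
    "first": [1, 2101, 15968, 16501, 33901],
    "last": [2100, 15967, 16500, 33900, 35991]
  },
  "epitopes": {
    "name": ["T12", "MIR", "A170", "M8M10"],
    "first": [2174, 15968, 33496, 35553],
    "last": [2437, 16348, 33784, 35991]
  }
}
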