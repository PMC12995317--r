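{
  "sizes": [40, 40, 40],
  "J": [
    [0.7, -0.2, 0.2],
    [-0.2, 0.6, 0.1],
    [0.2, 0.1, 0.5]
  ],
  "seed": 1
}
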