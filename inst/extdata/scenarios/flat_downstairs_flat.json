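{
  "segments": [
    {"terrain": "flat", "n_strides": 7},
    {"terrain": "downstairs", "n_strides": 6},
    {"terrain": "flat", "n_strides": 7}
  ]
}
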