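{
  "device": "synthetic-reference-device (placeholder values, NOT measured hardware)",
  "retspl_db": {
    "500": 6.0,
    "1000": 6.0,
    "2000": 7.5,
    "4000": 9.5
  },
  "max_output_spl_db": {
    "500": 100.0,
    "1000": 102.0,
    "2000": 101.0,
    "4000": 99.0
  },
  "volume_policy": "full-scale"
}
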