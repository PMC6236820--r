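{
  "format_version": "1",
  "reference_rx_Gy_RBE": 50.4,
  "margins_mm": {
    "20": 11,
    "5": 22
  }
}
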