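city:
  pop_under14: 2410000.0
  pop_15_64: 18075000.0
  pop_over65: 3615000.0
  hospitals: 338.0
  beds: 113000.0
  staff: 178000.0
  ac_rate: 0.95
  income: 3650.0
  allowance: 790.0
  insurance: 0.95
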