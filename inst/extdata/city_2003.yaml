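city:
  pop_under14: 2000000.0
  pop_15_64: 14200000.0
  pop_over65: 1900000.0
  hospitals: 290.0
  beds: 80000.0
  staff: 120000.0
  ac_rate: 0.7
  income: 1250.0
  allowance: 290.0
  insurance: 0.6
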