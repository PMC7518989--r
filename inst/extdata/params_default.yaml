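exposure:
  t_morb: 36.600000000000001
  t_mort: 37.600000000000001
  beta_morb: 4.321104262469114
  r_base: 24.939824736753739
  mu: 0.007030382982548
  vuln_over65: 1.0
  cf_on_apf: no
adaptation:
  af0: 0.199547332063418
  af_cap: 0.95
  factor_floor: 0.001
  factor_cap: 10.0
  weights:
    ac: 0.3
    income: 0.3
    staff: 0.3
    beds: 0.58023224281042
    hospitals: 0.2
    allowance: 0.658521955708272
    insurance: 0.3
  reference:
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
tables:
  MA:
  - - 35.0
    - 1.0
  - - 37.600000000000001
    - 1.0
  - - 38.799999999999997
    - 1.103853794049709
  - - 40.0
    - 1.720418118199172
  - - 40.399999999999999
    - 2.252340010857462
  - - 42.600000000000001
    - 2.571970667594427
  HDAF:
  - - 0.0
    - 1.0
  - - 7.0
    - 2.808241966847899
  - - 8.0
    - 5.863369123415203
  - - 12.0
    - 6.300443987909685
  - - 20.0
    - 9.557186025383464
background_rate: 114.0
initial_ap: 131608.991195259441156
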