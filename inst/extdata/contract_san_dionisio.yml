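station: San Dionisio INETER weather station
crop: Dry beans - drought tolerant type
soil: Deep sand
sowing_window:
- 135
- 166
sowing_rule:
  k: 5
  tau: 5.0
mwr:
- 0.0
- 10.0
- 10.0
- 25.0
- 40.0
- 40.0
- 40.0
- 30.0
- 0.0
trigger_mm: -70.0
premium: 3.0
indemnity_rate: 5.0
currency: USD

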