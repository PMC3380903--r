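# Demo pipeline configuration: 3 pixels x 2 soils x 30 years.
seed: 42
n_years: 30
pixels:
  - id: P1
    lat: 12.75
    lon: -85.85
  - id: P2
    lat: 12.90
    lon: -85.70
  - id: P3
    lat: 13.05
    lon: -85.55
climate:
  order: 3
  # droughty bimodal wet season: wet-day rain mean 10 mm, clustered spells,
  # mid-season dry spell in July-August
  p_wet: [0.05, 0.05, 0.05, 0.10, 0.44, 0.55, 0.55, 0.55, 0.55, 0.50, 0.15, 0.05]
  gamma_shape: 2.5
  gamma_scale: 4.0
  persistence: 0.35
  canicula_factor: 0.65
  canicula_window: [182, 243]
soils: [deep_loam, shallow_sand]
crop:
  potential_kg_ha: 2500
  noise_sd: 0.05
window:
  offset_days: -10
  n_dekads: 8
  sowing_window: [135, 166]
  sowing_rule:
    k: 5
    tau: 5
contract:
  station: San Dionisio reference station
  crop: Dry beans - drought tolerant type
  trigger_mm: -70
  indemnity_rate: 5
  premium: 3
  currency: USD
pricing:
  triggers_mm: [-50, -70]
  loading: 0
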