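# Default scenario run: Tmed preset over 1985-2070 on soil type 31 with
# the common four-crop rotation. Warm-up years 1985-1990 feed the first
# 7-year moving average reported for 1991.
scenario: Tmed
seed: 1
years: [1985, 2070]
soil:
  field_capacity_pct: 24
  awc_pct: 17
  wilting_pct: 7
  depth_cm: 60
  soil_type_id: "31"
policy:
  trigger_fraction: 0.20
  event_amount_mm: 20
  annual_cap_mm: 79
  cap_window_years: 7
  unit_convention: paper
rotation:
  crops: [Sugar beet, Potato, Winter rye, Winter barley]
  anchor_year: 1991
window:
  start_doy: 107
  start_swc_l_per_m3: 224.9
out_dir: runs/tmed_default
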