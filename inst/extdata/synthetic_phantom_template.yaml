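geometry:
  vial_radius_mm: 13.0
  vial_height_mm: 40.0
  ring_radii_mm:
  - 28.0
  - 58.0
vials:
- label: PVP0_centre
  pvp_percent: 0.0
  centre_offset_mm:
  - 0.0
  - 0.0
  ref_adc_um2_per_s: 1100.0
- label: PVP0_inner1
  pvp_percent: 0.0
  centre_offset_mm:
  - 28.0
  - 0.0
  ref_adc_um2_per_s: 1100.0
- label: PVP10_inner2
  pvp_percent: 10.0
  centre_offset_mm:
  - 14.0
  - 24.2487113
  ref_adc_um2_per_s: 900.0
- label: PVP20_inner3
  pvp_percent: 20.0
  centre_offset_mm:
  - -14.0
  - 24.2487113
  ref_adc_um2_per_s: 700.0
- label: PVP30_inner4
  pvp_percent: 30.0
  centre_offset_mm:
  - -28.0
  - 3.429011e-15
  ref_adc_um2_per_s: 500.0
- label: PVP40_inner5
  pvp_percent: 40.0
  centre_offset_mm:
  - -14.0
  - -24.2487113
  ref_adc_um2_per_s: 300.0
- label: PVP50_inner6
  pvp_percent: 50.0
  centre_offset_mm:
  - 14.0
  - -24.2487113
  ref_adc_um2_per_s: 200.0
- label: PVP10_outer1
  pvp_percent: 10.0
  centre_offset_mm:
  - 54.502172
  - 19.8371683
  ref_adc_um2_per_s: 900.0
- label: PVP20_outer2
  pvp_percent: 20.0
  centre_offset_mm:
  - 10.0715943
  - 57.1188497
  ref_adc_um2_per_s: 700.0
- label: PVP30_outer3
  pvp_percent: 30.0
  centre_offset_mm:
  - -44.4305777
  - 37.2816814
  ref_adc_um2_per_s: 500.0
- label: PVP40_outer4
  pvp_percent: 40.0
  centre_offset_mm:
  - -57.1188497
  - -10.0715943
  ref_adc_um2_per_s: 300.0
- label: PVP50_outer5
  pvp_percent: 50.0
  centre_offset_mm:
  - -10.0715943
  - -57.1188497
  ref_adc_um2_per_s: 200.0
- label: PVP0_outer6
  pvp_percent: 0.0
  centre_offset_mm:
  - 44.4305777
  - -37.2816814
  ref_adc_um2_per_s: 1100.0
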