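# Acquisition presets for the four scan configurations (overview body scan,
# head scan, and two detail settings). Thicknesses follow the published
# acquisition table; the bending-magnet field is configurable because it is
# not printed -- 0.85 T with a 6.03 GeV ring gives Ec ~ 20.6 keV.
head_53um:
  nominal_average_keV: 101
  source: {ring_energy_gev: 6.03, field_t: 0.85}
  filters:
    - {material: aluminium, thickness_mm: 50}   # 10 plates x 5 mm
    - {material: molybdenum, thickness_mm: 0.35}
  scintillator: {material: luag, thickness_um: 2000}
body_24um:
  nominal_average_keV: 139
  source: {ring_energy_gev: 6.03, field_t: 0.85}
  filters:
    - {material: molybdenum, thickness_mm: 0.3}
    - {material: copper, thickness_mm: 12}
  scintillator: {material: luag, thickness_um: 2000}
detail_6um:
  nominal_average_keV: 114
  source: {ring_energy_gev: 6.03, field_t: 0.85}
  filters:
    - {material: copper, thickness_mm: 6}
    - {material: molybdenum, thickness_mm: 0.4}
  scintillator: {material: ggg, thickness_um: 500}
plants_4um:
  nominal_average_keV: 120
  source: {ring_energy_gev: 6.03, field_t: 0.85}
  filters:
    - {material: aluminium, thickness_mm: 75}   # 15 plates x 5 mm
    - {material: molybdenum, thickness_mm: 0.35}
  scintillator: {material: luag, thickness_um: 200}
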