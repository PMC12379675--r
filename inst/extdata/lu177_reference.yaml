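# Reference lutetium-177 production scenario: 10 mA, 18 MeV deuterons on a
# 99 % enriched [176Yb]Yb2O3 disc designed for an 18 -> 8 MeV traversal,
# 5-day irradiation followed by 48 h of processing.
name: lu177_reference
beam:
  ion: d
  energy_mev: 18
  current_ma: 10
  transmission: 0.985
  radius_cm: 1
target:
  material:
    formula: Yb2O3
    density_g_cm3: 9.2
    molar_mass:
      Yb: 175.942574   # 176Yb isotopic mass; the target is 99 % enriched
    excitation_ev:
      Yb: 684
      O: 95
    name: "[176Yb]Yb2O3"
  radius_cm: 1
  exit_energy_mev: 8
  enrichment: 0.99
  active_element: Yb
rates:
  source: fixtures       # fixtures | reference
  datasets:              # dataset choice per reaction
    dp_yb177: nagai
    dn_lu177g: nagai
    dng_lu177m: tendl_dagger
    d2ng_lu176m: nagai
    d2n_lu176g: tendl_dagger
    d3n_lu175: tendl_dagger
    d4ng_lu174m: nagai
    d4n_lu174g: nagai
schedule:
  irradiation: {value: 5, unit: d}
  processing: {value: 48, unit: h}
  timeline_points: 25
report:
  nuclides: [lu177m, lu177g, lu176m, lu174m, lu174g]
  reference: lu177g
  specific_activity_basis: element
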