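# Minimal two-box fixture: one mixed water column over one sediment slab,
# a single parent -> product photo reaction, constant emission.
chemicals:
  - id: PAR
    molecular_weight: 200.0
    water_solubility: 1.0
    log_kow: 2.0
    pka: 5.0
    dissociation_class: acid
    koc_kow_ratio: 0.41
    property_mode: at_ph7
  - id: PROD
    molecular_weight: 180.0
    water_solubility: 2.0
    log_kow: 1.0
    pka: 5.0
    dissociation_class: acid
    koc_kow_ratio: 0.41
    property_mode: at_ph7
reactions:
  - {parent: PAR, product: PROD, kind: photo, half_life_h: 100}
  - {parent: PAR, product: other, kind: photo, half_life_h: 50}
  - {parent: PROD, product: other, kind: photo, half_life_h: 30}
compartments:
  - {id: W, medium: surface_water, volume: 10000, temperature: 15, ph: 7,
     ss_volume_fraction: 3.6e-5, ss_oc_fraction: 0.25,
     photolysis_multiplier: 1.0}
  - {id: SED, medium: bottom_sediment, volume: 20, temperature: 5, ph: 7,
     oc_fraction: 0.06, porosity: 0.8}
links:
  - {kind: advection, source: inflow, target: W, rate: 500}
  - {kind: advection, source: W, target: outflow, rate: 500}
  - {kind: sediment_exchange, source: W, target: SED, area: 1000,
     mtc_diff: 4.0e-4, u_dep: 1.0e-6, u_res: 4.0e-7, u_bur: 2.0e-7}
emissions:
  - {compartment: W, chemical: PAR, water_flow: 0, mol_h: 0.01}
options: {}
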