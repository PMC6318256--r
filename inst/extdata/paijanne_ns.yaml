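# Packaged stratified-lake N-S effluent-plume scenario.
# Parameters listed here are the scenario defaults; every key of
# paijanne_defaults() may be overridden (CLI: --override key=value).
builder: paijanne_ns
params:
  velocity_n: 1.0          # cm/s, western through-flow feeding the N area
  velocity_s_extra: 1.0    # cm/s, extra southern dilution inflow
  turnover_h: [0.014, 22, 1600, 16000, 16000]
  epilimnion_temp: 15.0    # degrees C, layers above the thermocline (L1-L3)
  hypolimnion_temp: 5.0    # degrees C, L4-L6 and sediments
  ph: 7.0
  ss_volume_fraction: 3.6e-5
  ss_oc_fraction: 0.25
  sediment_oc: 0.06
  sediment_thickness: 0.02 # m
  sediment_porosity: 0.8
  mtc_diff: 4.0e-4         # m/h diffusive sediment-water MTC
  u_dep: 1.0e-6            # m/h deposition
  u_res: 4.0e-7            # m/h resuspension
  u_bur: 2.0e-7            # m/h burial
  effluent_compartment: NL3
  effluent_flow: 1700      # m3/h
  effluent_conc_ug_l: {IBU: 1.0, DCF: 1.5, CBZ: 0.05}
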