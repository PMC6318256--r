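# Default one-at-a-time sensitivity survey for the packaged N-S scenario.
- {type: mixing, value: 0.1, label: "L1-L4 mixing rates to 10%",
   ids: [NL1, NL2, NL3, NL4, SL1, SL2, SL3, SL4]}
- {type: mixing, value: 2.0, label: "all mixing doubled"}
- {type: advection, value: 0.5, label: "western velocity halved"}
- {type: chemical, field: log_kow, action: add, value: 2.0,
   ids: [IBU, DCF], label: "IBU and DCF logKow + 2"}
- {type: temperature, action: set, value: 20.0, label: "all compartments 20 C"}
- {type: reaction_disable, ids: [photo], label: "no photolysis"}
- {type: reaction_disable, ids: [bio], label: "no biodegradation"}
- {type: reaction_rate, ids: tp_forming, value: 2.0,
   label: "TP-forming reaction rates doubled"}
- {type: suspended_solids, value: 2.0, label: "suspended sediments doubled"}
- {type: suspended_solids, value: 0.0, label: "suspended sediments removed"}
- {type: emission_target, value: NL2, label: "effluent input to NL2"}
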