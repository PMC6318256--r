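id,molecular_weight,water_solubility,log_kow,koc_kow_ratio,pka,dissociation_class,inherited
IBU,206.29,1.13,1.23,0.46,4.91,acid,
IBAP,176.26,5.37,1.34,0.46,4.91,acid,koc_kow_ratio;pka
IBU-CBX,236.26,130.13,0.14,0.46,3.97,acid,koc_kow_ratio
IBU-2OH,222.28,137.36,-0.29,0.46,4.63,acid,koc_kow_ratio
DCF,296.15,1.82,1.14,1.0,4.15,acid,
CPAB,231.68,3.28,0.77,1.0,4.15,acid,koc_kow_ratio;pka
5HDQI,310.13,38.17,0.60,1.0,3.60,acid,koc_kow_ratio
CBZ,236.27,0.075,2.7,5.4,13.9,acid,
AI,179.22,0.04,3.50,5.4,5.45,base,koc_kow_ratio
AO,195.22,0.10,3.21,5.4,13.9,acid,koc_kow_ratio;pka
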