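element,gain_counts_per_mmolcm2,line_energy_kev,yield
Ca,2000,3.69,0.163
P,800,2.01,0.063
Zn,5000,8.64,0.474
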