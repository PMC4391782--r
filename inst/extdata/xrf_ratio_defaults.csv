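tissue,ca_mmolcc,ca_p,ca_p_sd,ca_zn,ca_zn_sd
dentin,15.3,1.49,0.21,NA,NA
bone,11.1,1.68,0.20,2765,905
cementum,12.8,1.51,0.22,990,430
lesion_zone1,4.5,0.32,0.05,NA,NA
lesion_zone2,6.0,0.46,0.04,NA,NA
acellular_cementum,12.8,1.51,0.13,595,50
cellular_cementum,12.8,1.52,0.13,1155,165
bone_interface,11.1,1.68,0.20,855,125
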