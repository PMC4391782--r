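tissue,md_mean,md_sd,md_min,md_max
enamel,2957.5,68.75,2820,3095
dentin,1535,27.5,1480,1590
cementum,1290,15,1240,1340
bone,1115,30,570,1415
diseased_cementum,1150,50,1100,1220
hypomineralized_dentin,915,20,345,1450
hypermineralized_dentin,2255,50,1815,2740
calculus,1525,40,1290,1770
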