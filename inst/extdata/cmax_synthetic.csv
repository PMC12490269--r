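drug,cmax_uM
cobimetinib,0.5
regorafenib,8.1
linsitinib,1.5
vorinostat,1.2
venetoclax,2.6
navitoclax,4.7
pazopanib,72
dasatinib,0.2
ribociclib,4.3
panobinostat,0.05
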