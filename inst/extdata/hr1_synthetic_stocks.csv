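compartment_id,biomass,d13c_mean,d13c_sd
Det,NA,-25,1
DOC,NA,-24.5,1
Bac,80,-24,1.5
ChBac,30,-35,2
MacES,15,-35,2
MacDF,40,-24.5,2
MacSF,8,-24,1
MacPS,12,-24.5,2.5
MegDF,15,-24,1.5
MegSF,5,-24,1
Det_w,NA,-25,0.5
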