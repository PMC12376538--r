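species,mass_kda,mean_intensity,intensity_se
BSA,66,31.1,1.0
IgG,150,70.4,1.0
IgA,385,181.2,2.1
IgM,970,455.7,4.2
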