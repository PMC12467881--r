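species,wavelength_nm,rel_intensity,group,width_nm,peak_feature
CN,382.59,0.08,cn,0,FALSE
CN,382.84,0.12,cn,0,FALSE
CN,383.09,0.18,cn,0,FALSE
CN,383.34,0.27,cn,0,FALSE
CN,383.59,0.40,cn,0,FALSE
C-N,383.84,0.85,cn,0,TRUE
CN,386.93,0.15,cn,0,FALSE
CN,387.18,0.22,cn,0,FALSE
CN,387.43,0.33,cn,0,FALSE
C-N,387.68,0.70,cn,0,TRUE
Ca I,392.35,0.90,none,0,TRUE
Ca II,396.85,0.95,none,0,TRUE
Fe I,402.21,0.12,fe,0,FALSE
Fe I,402.46,0.18,fe,0,FALSE
Fe I,402.71,0.27,fe,0,FALSE
Fe I,402.96,0.50,fe,0,TRUE
Ca I,422.67,0.60,none,0,TRUE
Ca I,429.89,0.40,none,0,TRUE
Ca I,445.48,0.35,none,0,TRUE
Ca III,455.33,0.30,none,0,TRUE
V I,460.61,0.25,none,0,TRUE
C2,517.90,0.35,none,0,TRUE
V I,526.61,0.20,none,0,TRUE
Ca I,558.19,0.30,none,0,TRUE
Na I,588.99,0.80,none,0,TRUE
Ca I,612.22,0.35,none,0,TRUE
Ca I,616.22,0.30,none,0,TRUE
Ca I,643.91,0.25,none,0,TRUE
Ca I,646.26,0.25,none,0,TRUE
K I,766.49,1.00,k,0,TRUE
K I,769.90,0.85,k,0,TRUE
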