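subject_id,group,status,family_id,s,attenuation,age,sex
S0001,syndrome_01,molecular,F001,0.01,NA,43.11989813554101,male
S0002,syndrome_01,molecular,NA,0.01,NA,41.30222953669727,female
S0003,syndrome_01,molecular,NA,0.01,NA,6.852266564965248,female
S0004,syndrome_01,molecular,NA,0.01,NA,29.44860236882232,female
S0005,syndrome_02,molecular,NA,0.03,NA,43.321029253071174,male
S0006,syndrome_02,molecular,NA,0.03,NA,51.73923360207118,male
S0007,syndrome_02,molecular,NA,0.03,NA,40.525255345739424,male
S0008,syndrome_02,molecular,F002,0.03,NA,5.088894118089229,female
S0009,unaffected,unaffected,NA,0,NA,52.80619812454097,male
S0010,unaffected,unaffected,NA,0,NA,26.383946073474362,male
S0011,unaffected,unaffected,NA,0,NA,57.64248606096953,female
S0012,unaffected,unaffected,NA,0,NA,35.024281861959025,female
S0013,syndrome_01,relative,F001,0.005,0.5,38.6397099099122,female
S0014,syndrome_02,relative,F002,0.015,0.5,56.07608445780352,male
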