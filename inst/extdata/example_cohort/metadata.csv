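subject_id,age,sex,syndrome,diagnosis_status,family_id,camera,race,ethnicity
S0001,43.11989813554101,male,syndrome_01,molecular,F001,cam1,NA,NA
S0002,41.30222953669727,female,syndrome_01,molecular,NA,cam1,NA,NA
S0003,6.852266564965248,female,syndrome_01,molecular,NA,cam1,NA,NA
S0004,29.44860236882232,female,syndrome_01,molecular,NA,cam1,NA,NA
S0005,43.321029253071174,male,syndrome_02,molecular,NA,cam1,NA,NA
S0006,51.73923360207118,male,syndrome_02,molecular,NA,cam1,NA,NA
S0007,40.525255345739424,male,syndrome_02,molecular,NA,cam1,NA,NA
S0008,5.088894118089229,female,syndrome_02,molecular,F002,cam1,NA,NA
S0009,52.80619812454097,male,unaffected,unaffected,NA,cam1,NA,NA
S0010,26.383946073474362,male,unaffected,unaffected,NA,cam1,NA,NA
S0011,57.64248606096953,female,unaffected,unaffected,NA,cam1,NA,NA
S0012,35.024281861959025,female,unaffected,unaffected,NA,cam1,NA,NA
S0013,38.6397099099122,female,syndrome_01,relative,F001,cam1,NA,NA
S0014,56.07608445780352,male,syndrome_02,relative,F002,cam1,NA,NA
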