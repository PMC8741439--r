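patient_id,age,tumour_size,histology,grade,interval_days,e2_baseline,e2_post,ki67_bx,ki67_sx,ror_bx,ror_sx
CCI-002,74.9,1.4,1,2,49,30,994,6.7,6.2,62,52
CCI-003,71.2,1.3,1,2,39,30,1104,2.6,1.7,48,17
CCI-004,69.2,1.2,3,1,37,30,1560,8.9,5.2,ND,32
CCI-005,62.2,1.5,1,1,51,30,575,14.7,10.2,ND,30
CCI-006,60.1,1.1,1,2,42,30,168,4.0,0.6,48,15
CCI-010,67.2,1.4,1,2,35,41,1097,3.0,3.0,39,27
CCI-011,72.4,0.6,2,2,38,76,667,3.3,3.7,ND,33
CCI-012,59.4,2.8,5,1,51,39,470,13.5,5.1,53,53
CCI-013,62.3,0.7,1,1,42,<30,1041,2.4,1.0,63,18
CCI-014,58.3,1.4,1,1,28,<30,284,0.6,1.2,24,24
CCI-015,68.2,1.1,2,2,49,<30,1047,1.7,0.1,ND,37
CCI-016,60.6,0.6,3,1,42,<30,670,4.5,6.9,ND,62
CCI-017,55.4,1.3,5,2,66,<30,839,3.2,1.5,38,31
CCI-018,68.9,0.6,1,1,56,<30,1094,1.3,1.5,17,28
CCI-019,71.0,1.3,1,2,46,<30,817,1.4,0.6,ND,16
CCI-020,65.2,0.9,1,2,35,<30,595,2.1,1.3,48,41
CCI-021,63.0,1.5,1,2,37,46,780,9.6,7.1,50,56
CCI-022,69.7,1.6,2,2,41,57,1184,3.5,3.9,57,60
CCI-023,75.5,1.1,1,2,31,60,1200,4.8,4.5,51,46
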