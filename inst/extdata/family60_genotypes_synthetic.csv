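individual,locus,allele_1,allele_2
M13,RICA2a34,144,150
M13,RICA5,262,250
M13,Rrid013A,301,287
M13,Ga1a19,197,203
M13,RICA18,188,180
M13,RICA1b5,120,134
M13,Res14,140,146
M13,Res20,124,118
M13,Re1Caga10,95,110
M13,Re2Caga3,165,173
M13,RICA1b6,70,77
M13,Res22,79,85
M13,Rrid059A,125,129
M13,Rrid082A,158,163
M13,Rrid169A,180,187
F60,RICA2a34,150,152
F60,RICA5,250,256
F60,Rrid013A,287,293
F60,Ga1a19,207,211
F60,RICA18,180,184
F60,RICA1b5,136,140
F60,Res14,146,150
F60,Res20,118,122
F60,Re1Caga10,106,108
F60,Re2Caga3,204,212
F60,RICA1b6,80,83
F60,Res22,106,113
F60,Rrid059A,131,135
F60,Rrid082A,169,178
F60,Rrid169A,189,192
JUV01,RICA2a34,150,144
JUV01,RICA5,256,262
JUV01,Rrid013A,287,301
JUV01,Ga1a19,211,197
JUV01,RICA18,180,188
JUV01,RICA1b5,140,120
JUV01,Res14,146,140
JUV01,Res20,122,124
JUV01,Re1Caga10,106,95
JUV01,Re2Caga3,212,165
JUV01,RICA1b6,80,70
JUV01,Res22,113,79
JUV01,Rrid059A,131,125
JUV01,Rrid082A,178,158
JUV01,Rrid169A,189,180
JUV02,RICA2a34,152,144
JUV02,RICA5,250,262
JUV02,Rrid013A,293,301
JUV02,Ga1a19,207,197
JUV02,RICA18,184,188
JUV02,RICA1b5,136,120
JUV02,Res14,150,140
JUV02,Res20,118,124
JUV02,Re1Caga10,108,95
JUV02,Re2Caga3,204,165
JUV02,RICA1b6,83,70
JUV02,Res22,106,79
JUV02,Rrid059A,135,125
JUV02,Rrid082A,169,158
JUV02,Rrid169A,192,180
JUV03,RICA2a34,150,144
JUV03,RICA5,256,262
JUV03,Rrid013A,287,301
JUV03,Ga1a19,211,197
JUV03,RICA18,180,188
JUV03,RICA1b5,140,120
JUV03,Res14,146,140
JUV03,Res20,122,124
JUV03,Re1Caga10,106,95
JUV03,Re2Caga3,212,165
JUV03,RICA1b6,80,70
JUV03,Res22,113,79
JUV03,Rrid059A,131,125
JUV03,Rrid082A,178,158
JUV03,Rrid169A,189,180
JUV04,RICA2a34,152,144
JUV04,RICA5,250,262
JUV04,Rrid013A,293,301
JUV04,Ga1a19,207,197
JUV04,RICA18,184,188
JUV04,RICA1b5,136,120
JUV04,Res14,150,140
JUV04,Res20,118,124
JUV04,Re1Caga10,108,95
JUV04,Re2Caga3,204,165
JUV04,RICA1b6,83,70
JUV04,Res22,106,79
JUV04,Rrid059A,135,125
JUV04,Rrid082A,169,158
JUV04,Rrid169A,192,180
JUV05,RICA2a34,150,144
JUV05,RICA5,256,262
JUV05,Rrid013A,287,301
JUV05,Ga1a19,211,197
JUV05,RICA18,180,188
JUV05,RICA1b5,140,120
JUV05,Res14,146,140
JUV05,Res20,122,124
JUV05,Re1Caga10,106,95
JUV05,Re2Caga3,212,165
JUV05,RICA1b6,80,70
JUV05,Res22,113,79
JUV05,Rrid059A,131,125
JUV05,Rrid082A,178,158
JUV05,Rrid169A,189,180
JUV06,RICA2a34,152,144
JUV06,RICA5,250,262
JUV06,Rrid013A,293,301
JUV06,Ga1a19,207,197
JUV06,RICA18,184,188
JUV06,RICA1b5,136,120
JUV06,Res14,150,140
JUV06,Res20,118,124
JUV06,Re1Caga10,108,95
JUV06,Re2Caga3,204,165
JUV06,RICA1b6,83,70
JUV06,Res22,106,79
JUV06,Rrid059A,135,125
JUV06,Rrid082A,169,158
JUV06,Rrid169A,192,180
JUV07,RICA2a34,150,144
JUV07,RICA5,256,262
JUV07,Rrid013A,287,301
JUV07,Ga1a19,211,197
JUV07,RICA18,180,188
JUV07,RICA1b5,140,120
JUV07,Res14,146,140
JUV07,Res20,122,124
JUV07,Re1Caga10,106,95
JUV07,Re2Caga3,212,165
JUV07,RICA1b6,80,70
JUV07,Res22,113,79
JUV07,Rrid059A,131,125
JUV07,Rrid082A,178,158
JUV07,Rrid169A,189,180
JUV19,RICA2a34,152,144
JUV19,RICA5,250,262
JUV19,Rrid013A,293,301
JUV19,Ga1a19,207,197
JUV19,RICA18,184,188
JUV19,RICA1b5,136,120
JUV19,Res14,150,140
JUV19,Res20,118,124
JUV19,Re1Caga10,108,110
JUV19,Re2Caga3,204,165
JUV19,RICA1b6,83,70
JUV19,Res22,106,79
JUV19,Rrid059A,135,125
JUV19,Rrid082A,169,158
JUV19,Rrid169A,192,180
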