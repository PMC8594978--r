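*NEWRECORD
RECTYPE = D
MH = DNA Repair
MN = G02.111.222
MN = G05.219
*NEWRECORD
RECTYPE = D
MH = Genetic Diseases, Inborn
MN = C16.320
*NEWRECORD
RECTYPE = D
MH = DNA Damage
MN = G02.111.221
*NEWRECORD
RECTYPE = D
MH = Mutation
MN = G05.365.590
*NEWRECORD
RECTYPE = D
MH = Neoplasms
MN = C04
*NEWRECORD
RECTYPE = D
MH = Colonic Neoplasms
MN = C04.588.274.476.411.307
*NEWRECORD
RECTYPE = D
MH = Apoptosis
MN = G04.299.139
*NEWRECORD
RECTYPE = D
MH = Cell Cycle
MN = G04.299.134
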