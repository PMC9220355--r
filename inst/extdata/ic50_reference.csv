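inhibitor,assay,ic50_mM,se
oxalic acid,hydrocoerulignone,1.1,0.1
oxalic acid,"2,6-DMP",1.0,0.1
glyoxylic acid,hydrocoerulignone,7.1,0.2
glyoxylic acid,"2,6-DMP",3.7,0.6
pyruvic acid,hydrocoerulignone,17.2,1.0
pyruvic acid,"2,6-DMP",12.4,0.8
citric acid,hydrocoerulignone,1.8,0.3
citric acid,"2,6-DMP",2.7,0.2
histidine,hydrocoerulignone,1.0,0.1
histidine,"2,6-DMP",2.0,0.1
histamine,hydrocoerulignone,8.5,0.4
histamine,"2,6-DMP",16.3,0.7
glycine,hydrocoerulignone,115,20
glycine,"2,6-DMP",109,6
asparagine,hydrocoerulignone,24.9,0.2
asparagine,"2,6-DMP",45.8,2.8
phenylalanine,hydrocoerulignone,23.8,1.1
phenylalanine,"2,6-DMP",32.4,3.7
sodium sulfate,hydrocoerulignone,31.2,4.7
sodium sulfate,"2,6-DMP",32.8,3.2
sodium fluoride,hydrocoerulignone,142,39
sodium fluoride,"2,6-DMP",316,17
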