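inhibitor,assay,specific_activity_U_per_g,sd,residual_printed_pct,residual_sd
acetic acid,hydrocoerulignone,97.4,7.2,70.8,5.2
acetic acid,"2,6-DMP",17.5,1.5,76.5,6.6
lactic acid,hydrocoerulignone,67.6,10.2,49.2,7.4
lactic acid,"2,6-DMP",6.4,0.3,28.1,1.3
glyoxal,hydrocoerulignone,60.5,4.9,43.9,3.6
glyoxal,"2,6-DMP",4.8,0.3,20.8,1.5
pyruvic acid,hydrocoerulignone,5.6,0.6,4.1,0.4
pyruvic acid,"2,6-DMP",0.1,0.1,0.1,0.1
glyoxylic acid,hydrocoerulignone,1.5,0.4,1.1,0.3
glyoxylic acid,"2,6-DMP",0.1,0.1,0.1,0.1
oxalic acid,hydrocoerulignone,0.8,0.2,0.6,0.1
oxalic acid,"2,6-DMP",0.1,0.1,0.1,0.1
citric acid,hydrocoerulignone,2.0,0.5,1.5,0.4
citric acid,"2,6-DMP",0.3,0.1,1.3,0.4
imidazole,hydrocoerulignone,99.4,5.4,72.2,3.9
imidazole,"2,6-DMP",18.3,1.1,80.0,4.8
glycine,hydrocoerulignone,67.7,1.6,49.2,1.2
glycine,"2,6-DMP",10.1,0.8,44.1,3.5
histamine,hydrocoerulignone,2.2,0.6,1.6,0.4
histamine,"2,6-DMP",0.8,0.3,3.5,1.3
histidine,hydrocoerulignone,0.5,0.3,0.4,0.2
histidine,"2,6-DMP",0.1,0.1,0.1,0.1
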