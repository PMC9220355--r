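ligand,N_im_MeHis1,N_am_MeHis1,N_im_His83,O_Tyr166,L_eq,L_ax,note
water,1.95,2.05,1.97,2.44,2.07,2.39,
glycine,1.96,2.06,1.97,2.35,2.01,2.80,
asparagine,1.96,2.03,2.01,2.41,1.95,3.01,
phenylalanine,1.96,2.04,1.95,2.34,2.00,3.90,average to phenyl ring carbons
histamine,2.01,2.06,2.04,2.79,2.04,2.19,
pyruvic acid (pose A),1.95,2.08,1.98,2.81,2.43,1.98,
glyoxylic acid (pose B),1.97,2.05,1.99,2.51,1.96,2.53,
glyoxylic acid (pose A),1.96,2.07,1.97,2.36,1.96,NA,position not occupied
pyruvic acid (pose B),1.97,2.04,1.99,2.63,1.96,2.41,
histidine (C-linked),2.01,2.06,2.04,2.83,2.00,2.20,
histidine (N-linked),1.94,2.05,1.96,2.71,1.91,NA,position not occupied
oxalic acid,1.98,2.07,2.02,3.02,1.98,2.15,
citric acid,1.98,2.06,2.01,3.36,1.95,2.16,
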