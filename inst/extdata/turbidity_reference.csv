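inhibitor,rate_per_min,sd,residual_printed_pct,residual_sd
acetic acid,0.14,0.01,84,5
phosphoric acid,0.107,0.02,65,10
lactic acid,0.08,0.02,47,13
citric acid,0.014,0.001,8,1
oxalic acid,0.002,0.001,1.4,0.6
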