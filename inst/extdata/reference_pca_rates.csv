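component,contribution_pct
PC1,56.95
PC2,24.70
PC3,7.95
PC4,7.27
PC5,2.42
PC6,0.70
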