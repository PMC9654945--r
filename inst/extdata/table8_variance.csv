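component,percent
pc1,60.98
pc2,18.43
pc3,6.99
pc4,5.51
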