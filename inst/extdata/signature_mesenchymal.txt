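VIM
ZEB1
ZEB2
SNAI1
SNAI2
TWIST1
FN1
CDH2
FOXC2
MMP2
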