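CDH1
EPCAM
GRHL2
ESRP1
OVOL2
KRT8
KRT18
CLDN4
DSP
OCLN
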