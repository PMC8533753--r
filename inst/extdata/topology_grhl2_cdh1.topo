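Source Target Type
SNAIL SLUG 2
SLUG SNAIL 2
SNAIL ZEB1 1
SLUG ZEB1 1
SNAIL miR200 2
SLUG miR200 2
miR200 SLUG 2
ZEB1 miR200 2
miR200 ZEB1 2
ZEB1 ZEB1 1
SNAIL SNAIL 2
GRHL2 ZEB1 2
ZEB1 GRHL2 2
ZEB1 CDH1 2
SLUG CDH1 2
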