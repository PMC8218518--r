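histology	count
Serous	114
Endometrioid	53
Clear cell	14
Undifferentiated	8
Mucinous	3
Other	3
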