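compound,st_r_min,reference
Chonglou saponin VII,19.803,TRUE
Chonglou saponin VI,22.156,FALSE
Chonglou saponin II,30.319,FALSE
Chonglou saponin I,33.035,TRUE
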