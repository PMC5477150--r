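compound,rr,reference
Chonglou saponin VII,0.652,FALSE
Chonglou saponin VI,0.729,FALSE
Chonglou saponin II,1.000,TRUE
Chonglou saponin I,1.090,FALSE
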