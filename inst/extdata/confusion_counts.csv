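model,tp,tn,fp,fn
cpcnn,548,654,62,132
single_low,558,627,89,122
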