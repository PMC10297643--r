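reader,total,correct
attending1,200,181
attending2_cnn,200,195
chief2,200,191
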