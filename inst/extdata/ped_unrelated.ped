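U1 0 0 1
U2 0 0 1
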