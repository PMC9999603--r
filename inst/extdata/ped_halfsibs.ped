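MO 0 0 0
FA1 0 0 0
FA2 0 0 0
CH1 FA1 MO 1
CH2 FA2 MO 1
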