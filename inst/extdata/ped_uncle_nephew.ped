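GF 0 0 0
GM 0 0 0
UN GF GM 1
FA GF GM 0
MO 0 0 0
NE FA MO 1
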