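treatment,spacing_cm,pruning
CK,55,1V1F
T1,55,2V2F
T2,55,3V3F
T3,55,3V2F
T4,65,2V2F
T5,65,3V3F
T6,65,3V2F
T7,75,2V2F
T8,75,3V3F
T9,75,3V2F
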