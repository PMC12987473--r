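treatment,yield_t_hm2,yield_rank
CK,27.86,10
T1,,3
T2,,2
T3,53.97,1
T4,,5
T5,,6
T6,,4
T7,,8
T8,,9
T9,,7
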