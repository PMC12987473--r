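treatment,d_plus,d_minus,ci,rank
CK,0.214,0.119,0.357,7
T1,0.310,0.026,0.077,9
T2,0.331,0.010,0.029,10
T3,0.283,0.058,0.170,8
T4,0.137,0.197,0.589,5
T5,0.157,0.177,0.530,6
T6,0.129,0.203,0.611,4
T7,0.023,0.322,0.933,2
T8,0.029,0.319,0.916,3
T9,0.023,0.330,0.935,1
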