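treatment,sowing_date,emergence_date,vine_elongation_date,female_flower_date,fruit_set_date,enlargement_date,maturity_date,fruit_development_days,total_growth_days
CK,2023/3/18,2023/4/2,2023/5/1,2023/5/19,2023/5/25,2023/6/10,2023/6/26,33,101
T1,2023/3/18,2023/4/1,2023/5/1,2023/5/22,2023/5/27,2023/6/17,2023/7/5,40,110
T2,2023/3/18,2023/4/2,2023/5/1,2023/5/22,2023/5/28,2023/6/25,2023/7/14,48,119
T3,2023/3/18,2023/4/1,2023/4/29,2023/5/23,2023/5/29,2023/6/23,2023/7/14,47,119
T4,2023/3/18,2023/3/30,2023/4/30,2023/5/21,2023/5/27,2023/6/16,2023/7/4,39,109
T5,2023/3/18,2023/3/30,2023/4/26,2023/5/21,2023/5/28,2023/6/23,2023/7/13,47,118
T6,2023/3/18,2023/3/31,2023/4/28,2023/5/19,2023/5/27,2023/6/21,2023/7/12,47,117
T7,2023/3/18,2023/3/31,2023/4/30,2023/5/21,2023/5/27,2023/6/16,2023/7/2,37,107
T8,2023/3/18,2023/3/30,2023/4/30,2023/5/21,2023/5/29,2023/6/23,2023/7/13,46,118
T9,2023/3/18,2023/3/31,2023/4/26,2023/5/20,2023/5/28,2023/6/22,2023/7/13,47,118
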