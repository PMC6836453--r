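subject,age_y,height_cm,weight_kg,preferred_speed_m_s,slow_speed_m_s
1,44,170,72,1.05,0.83
2,55,183,75,1.16,1.03
3,64,165,70,0.98,0.85
4,52,178,70,1.24,0.89
5,45,189,88,1.28,0.69
6,55,180,78,1.33,0.83
7,47,174,85,1.33,1.02
8,47,188,90,1.18,0.78
9,51,176,75,1.16,0.87
10,52,168,80,1.44,1.13
11,71,174,79,1.41,1.00
12,60,168,77,1.46,1.03
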