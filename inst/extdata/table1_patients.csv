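subject,prosthetic_knee,age_y,height_cm,weight_kg,speed_m_s
1,C-Leg,56,175,72,0.93
2,C-Leg,74,170,85,0.76
3,C-Leg,72,163,87,0.80
4,C-Leg,52,178,115,0.79
5,C-Leg,53,183,67,0.82
6,C-Leg,39,175,95,0.75
7,C-Leg,36,170,70,1.17
8,Genium,49,178,100,0.82
9,Genium,29,172,65,1.12
10,Genium,59,170,80,0.97
11,Genium,44,192,103,1.16
12,Genium,48,174,90,1.08
13,Genium,69,175,76,0.45
14,Genium,30,178,95,0.98
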