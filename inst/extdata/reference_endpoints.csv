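region,stage,value_2024,value_2040,printed_decline_pct
Sichuan,preschool,62.56,19.47,68.9
Yunnan,preschool,58.95,18.34,68.9
Qinghai,preschool,8.85,2.74,69.0
Chongqing,primary,13.48,4.20,68.8
Xizang,primary,6.99,2.16,69.1
Gansu,junior,32.53,10.10,68.9
Qinghai,junior,8.85,2.74,69.0
Chongqing,junior_teachers,2.24,1.36,39.3
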