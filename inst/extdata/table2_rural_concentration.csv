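year,preschool,primary,junior
2024,17.68,19.04,9.21
2025,16.79,18.67,8.96
2026,15.94,18.30,8.71
2027,15.12,17.93,8.46
2028,14.34,17.56,8.21
2029,13.59,17.19,7.96
2030,12.88,16.82,7.71
2031,12.20,16.45,7.46
2032,11.55,16.08,7.21
2033,10.94,15.71,6.96
2034,10.35,15.34,6.71
2035,10.13,14.97,6.46
2036,9.85,14.60,6.21
2037,9.43,14.23,5.96
2038,8.78,13.86,5.71
2039,8.46,13.49,5.46
2040,8.15,13.12,5.21
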