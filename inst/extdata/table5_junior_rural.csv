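year,Chongqing,Sichuan,Yunnan,Guizhou,Xizang,Shaanxi,Gansu,Ningxia,Qinghai,Xinjiang,Neimenggu,Guangxi
2024,2.24,10.38,9.78,7.99,1.15,8.48,5.39,1.71,1.46,5.56,3.22,8.89
2025,2.20,10.19,9.61,7.84,1.13,8.32,5.29,1.68,1.44,5.46,3.17,8.71
2026,2.16,10.02,9.42,7.71,1.11,8.17,5.20,1.65,1.41,5.23,3.11,8.53
2027,2.12,9.82,9.24,7.56,1.04,7.89,5.07,1.52,1.38,5.26,3.05,8.37
2028,2.08,9.64,9.06,7.41,1.07,7.85,4.99,1.59,1.36,5.16,2.99,8.21
2029,2.04,9.44,8.88,7.26,1.05,7.69,4.91,1.56,1.33,5.05,2.92,8.02
2030,1.99,9.23,8.69,7.12,1.03,7.53,4.80,1.53,1.30,4.94,2.86,7.84
2031,1.95,9.02,8.49,6.94,1.00,7.35,4.69,1.49,1.27,4.83,2.79,7.66
2032,1.90,8.80,8.29,6.78,0.98,7.18,4.58,1.46,1.24,4.71,2.72,7.47
2033,1.82,8.47,7.99,6.48,0.94,6.88,4.41,1.39,1.19,4.52,2.62,7.20
2034,1.72,8.01,7.54,6.12,0.89,6.51,4.17,1.31,1.13,4.28,2.48,6.80
2035,1.58,7.39,6.97,5.65,0.82,6.01,3.87,1.21,1.04,3.93,2.28,6.28
2036,1.51,7.04,6.64,5.38,0.79,5.73,3.67,1.16,0.99,3.75,2.18,5.99
2037,1.46,6.78,6.39,5.19,0.76,5.52,3.54,1.11,0.95,3.61,2.10,5.76
2038,1.45,6.73,6.35,5.15,0.75,5.49,3.51,1.07,0.91,3.60,2.08,5.73
2039,1.39,6.42,6.05,4.91,0.72,5.23,3.36,1.05,0.90,3.43,1.98,5.46
2040,1.36,6.28,5.91,4.80,0.70,5.11,3.28,1.03,0.88,3.36,1.95,5.35
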