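year,Chongqing,Sichuan,Yunnan,Guizhou,Xizang,Shaanxi,Gansu,Ningxia,Qinghai,Xinjiang,Neimenggu,Guangxi
2024,13.48,62.56,58.95,47.73,6.99,50.85,32.53,10.38,8.85,33.73,19.55,54.09
2025,12.50,57.99,54.61,44.23,6.47,47.17,30.20,9.63,8.21,31.29,18.14,50.16
2026,11.45,53.15,50.06,40.57,5.93,43.17,27.64,8.82,7.53,28.68,16.63,45.93
2027,10.75,49.85,46.98,38.10,5.56,40.53,25.94,8.28,7.06,26.93,15.60,43.06
2028,10.36,48.08,45.29,36.70,5.36,39.11,25.06,8.02,6.82,25.96,15.06,41.54
2029,10.05,46.59,43.92,35.61,5.20,37.94,24.28,7.76,6.61,25.18,14.61,40.31
2030,9.51,44.07,41.57,33.65,4.91,35.89,22.96,7.34,6.25,23.81,13.81,38.11
2031,9.10,42.99,39.78,32.40,4.70,34.32,21.98,7.01,5.98,22.79,13.23,36.66
2032,8.61,39.93,37.63,30.45,4.45,32.48,20.79,6.64,5.66,21.56,12.50,34.49
2033,7.98,36.99,34.85,28.20,4.12,30.07,19.23,6.14,5.23,19.92,11.57,31.91
2034,6.95,32.26,30.40,24.63,3.59,26.19,16.77,5.36,4.57,17.39,10.09,27.81
2035,6.39,29.61,27.88,22.60,3.29,24.05,15.39,4.92,4.19,15.94,9.25,25.49
2036,5.90,27.35,25.79,20.89,3.04,22.18,14.20,4.54,3.86,14.68,8.53,23.50
2037,5.41,25.08,23.64,19.16,2.79,20.35,13.01,4.16,3.53,13.45,7.82,21.56
2038,4.80,22.25,21.20,16.99,2.48,18.06,11.54,3.69,3.14,11.93,6.94,19.12
2039,4.55,21.14,19.89,16.12,2.35,17.11,10.93,3.49,2.97,11.29,6.56,18.09
2040,4.21,19.47,18.34,14.86,2.16,15.79,10.10,3.23,2.74,10.43,6.06,16.69
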