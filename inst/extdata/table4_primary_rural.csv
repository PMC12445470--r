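year,Chongqing,Sichuan,Yunnan,Guizhou,Xizang,Shaanxi,Gansu,Ningxia,Qinghai,Xinjiang,Neimenggu,Guangxi
2024,12.47,58.17,53.73,44.60,6.88,48.08,30.90,9.94,8.42,26.92,18.12,50.70
2025,12.86,53.66,49.03,38.66,6.72,42.41,28.54,9.79,8.39,31.20,18.29,44.80
2026,11.83,53.48,50.17,40.67,6.22,44.12,27.29,9.20,7.69,28.68,16.76,46.67
2027,11.54,52.15,48.93,39.64,5.95,43.21,27.01,8.81,7.31,27.98,16.36,45.27
2028,11.14,50.83,47.73,38.61,5.75,41.89,26.49,8.59,6.91,27.25,15.94,44.21
2029,10.83,49.01,46.02,37.20,5.67,40.43,25.52,8.28,7.04,26.32,15.38,42.35
2030,10.52,47.60,44.69,36.16,5.50,39.26,24.82,8.04,6.84,25.51,14.93,41.11
2031,10.26,46.38,43.52,35.17,5.37,38.55,24.22,7.85,6.68,24.86,14.60,40.22
2032,9.93,44.91,42.18,34.11,5.20,37.37,23.45,7.60,6.47,24.10,14.13,38.92
2033,9.64,43.58,40.93,33.07,4.96,36.28,22.80,7.39,6.28,23.41,13.70,37.77
2034,9.61,43.35,40.68,32.89,5.03,36.04,22.62,7.34,6.25,23.26,13.62,37.50
2035,9.48,42.82,40.18,32.47,4.96,35.62,22.35,7.25,6.16,22.95,13.44,37.06
2036,9.12,41.13,38.58,31.22,4.77,34.23,21.47,6.96,5.90,22.16,12.79,35.30
2037,8.66,39.10,36.60,29.61,4.51,32.39,20.30,6.58,5.59,20.86,12.13,33.29
2038,8.16,36.75,34.47,27.88,4.25,30.45,19.14,6.21,5.27,19.68,11.44,31.34
2039,7.66,34.50,32.38,26.18,3.99,28.63,17.98,5.83,4.96,18.49,10.75,29.52
2040,6.98,31.57,29.64,23.95,3.64,26.20,16.44,5.34,4.53,16.92,9.83,26.96
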