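year,age_3,age_4,age_5,preschool_total,age_6,age_7,age_8,age_9,age_10,age_11,primary_total,age_12,age_13,age_14,junior_total
2024,329.4,343.5,340.4,1013.3,337.4,334.3,331.2,328.1,325.0,321.6,1977.6,318.9,315.8,312.8,947.5
2025,321.7,329.4,343.5,994.6,340.4,337.4,334.3,331.2,328.1,325.0,1996.4,321.6,318.9,315.8,956.3
2026,302.4,321.7,329.4,953.5,343.5,340.4,337.4,334.3,331.2,328.1,2014.9,325.0,321.6,318.9,965.5
2027,322.8,302.4,321.7,946.9,329.4,343.5,340.4,337.4,334.3,331.2,2016.2,328.1,325.0,321.6,974.7
2028,334.3,322.8,302.4,959.5,321.7,329.4,343.5,340.4,337.4,334.3,2006.7,331.2,328.1,325.0,984.3
2029,326.5,334.3,322.8,983.6,302.4,321.7,329.4,343.5,340.4,337.4,1974.8,334.3,331.2,328.1,993.6
2030,319.3,326.5,334.3,980.1,322.8,302.4,321.7,329.4,343.5,340.4,1960.2,337.4,334.3,331.2,1002.9
2031,358.4,319.3,326.5,1004.2,334.3,322.8,302.4,321.7,329.4,343.5,1954.1,340.4,337.4,334.3,1012.1
2032,325.7,358.4,319.3,1003.4,326.5,334.3,322.8,302.4,321.7,329.4,1937.1,343.5,340.4,337.4,1021.3
2033,298.4,325.7,358.4,982.5,319.3,326.5,334.3,322.8,302.4,321.7,1927.0,329.4,343.5,340.4,1013.3
2034,283.1,298.4,325.7,907.2,358.4,319.3,326.5,334.3,322.8,302.4,1963.7,321.7,329.4,343.5,994.6
2035,264.2,283.1,298.4,845.7,325.7,358.4,319.3,326.5,334.3,322.8,1987.4,302.4,321.7,329.4,953.5
2036,255.9,264.2,283.1,803.2,298.4,325.7,358.4,319.3,326.5,334.3,1962.6,322.8,302.4,321.7,946.9
2037,248.6,255.9,264.2,768.7,283.1,298.4,325.7,358.4,319.3,326.5,1911.4,334.3,322.8,302.4,959.5
2038,233.5,248.6,255.9,738.2,264.2,283.1,298.4,325.7,358.4,319.3,1849.1,326.5,334.3,322.8,983.6
2039,247.6,233.5,248.6,729.7,255.9,264.2,283.1,298.4,325.7,358.4,1785.7,319.3,326.5,334.3,980.1
2040,215.3,247.6,233.5,696.4,248.6,255.9,264.2,283.1,298.4,325.7,1675.9,358.4,319.3,326.5,1004.2
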