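source_table,exposure1,exposure2,e1,e2,cases,controls,printed_or,printed_ci_low,printed_ci_high
table2,family_history,diabetes,0,0,30,95,1.000,NA,NA
table2,family_history,diabetes,0,1,22,16,4.354,2.086,9.076
table2,family_history,diabetes,1,0,175,123,4.505,2.866,7.084
table2,family_history,diabetes,1,1,187,36,16.537,10.070,21.157
table3,family_history,drinking,0,0,42,84,1.000,NA,NA
table3,family_history,drinking,0,1,10,27,0.741,0.329,1.669
table3,family_history,drinking,1,0,257,104,4.942,3.258,7.497
table3,family_history,drinking,1,1,106,53,4.000,2.461,6.502
table4,family_history,sports,0,0,7,24,1.000,NA,NA
table4,family_history,sports,0,1,45,87,1.773,0.716,4.395
table4,family_history,sports,1,0,70,28,8.571,3.586,20.487
table4,family_history,sports,1,1,291,131,7.668,3.598,16.344
table5,family_history,taste,0,0,41,93,1.000,NA,NA
table5,family_history,taste,0,1,11,18,1.386,0.603,3.187
table5,family_history,taste,1,0,270,127,4.840,3.227,7.260
table5,family_history,taste,1,1,92,32,6.521,3.858,11.024
table6,family_history,smoking,0,0,38,78,1.000,NA,NA
table6,family_history,smoking,0,1,14,33,0.871,0.417,1.816
table6,family_history,smoking,1,0,222,105,4.359,2.820,6.739
table6,family_history,smoking,1,1,140,52,5.526,3.404,8.972
table7,family_history,pressure,0,0,48,107,1.000,NA,NA
table7,family_history,pressure,0,1,4,4,2.229,0.552,8.997
table7,family_history,pressure,1,0,329,141,5.217,3.585,7.592
table7,family_history,pressure,1,1,33,18,4.087,2.144,7.788
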