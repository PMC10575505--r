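category,province,year,rate_per_1000,n_prescriptions
guideline_adherent,BC,2014,2.16,85
guideline_adherent,BC,2015,2.89,129
guideline_adherent,BC,2016,3.54,155
guideline_adherent,BC,2017,4.74,233
guideline_adherent,BC,2018,6.93,329
guideline_adherent,ON,2014,0.37,42
guideline_adherent,ON,2015,0.56,68
guideline_adherent,ON,2016,0.74,82
guideline_adherent,ON,2017,1.26,155
guideline_adherent,ON,2018,1.86,242
clinically_appropriate,BC,2014,159.92,6561
clinically_appropriate,BC,2015,157.89,6947
clinically_appropriate,BC,2016,158.12,6859
clinically_appropriate,BC,2017,145.55,7109
clinically_appropriate,BC,2018,127.80,6010
clinically_appropriate,ON,2014,231.47,23671
clinically_appropriate,ON,2015,224.87,24784
clinically_appropriate,ON,2016,217.43,23210
clinically_appropriate,ON,2017,206.99,25367
clinically_appropriate,ON,2018,199.10,25213
effective_but_unnecessary,BC,2014,36.50,1414
effective_but_unnecessary,BC,2015,42.34,1774
effective_but_unnecessary,BC,2016,54.26,2185
effective_but_unnecessary,BC,2017,58.71,2695
effective_but_unnecessary,BC,2018,65.82,2913
effective_but_unnecessary,ON,2014,16.87,1680
effective_but_unnecessary,ON,2015,22.78,2478
effective_but_unnecessary,ON,2016,29.04,3017
effective_but_unnecessary,ON,2017,37.72,4524
effective_but_unnecessary,ON,2018,49.66,6159
undertreatment,BC,2014,25.10,1012
undertreatment,BC,2015,26.66,1164
undertreatment,BC,2016,28.59,1233
undertreatment,BC,2017,28.51,1375
undertreatment,BC,2018,26.88,1275
undertreatment,ON,2014,24.19,2479
undertreatment,ON,2015,28.00,3138
undertreatment,ON,2016,32.21,3436
undertreatment,ON,2017,34.11,4247
undertreatment,ON,2018,34.94,4541
not_recommended,BC,2014,19.20,670
not_recommended,BC,2015,18.27,693
not_recommended,BC,2016,20.26,731
not_recommended,BC,2017,19.56,807
not_recommended,BC,2018,20.81,812
not_recommended,ON,2014,13.27,1143
not_recommended,ON,2015,13.60,1259
not_recommended,ON,2016,12.97,1147
not_recommended,ON,2017,12.48,1286
not_recommended,ON,2018,12.72,1330
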