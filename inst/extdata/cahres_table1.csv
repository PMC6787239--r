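characteristic,level,cases_count,cases_pct,controls_count,controls_pct,cases_mean,cases_sd,controls_mean,controls_sd,p_value
number,,253,,728,,,,,,
hrt,never,152,60.1,572,78.6,,,,,1e-08
hrt,past,6,2.4,23,3.1,,,,,
hrt,current,95,37.5,133,18.3,,,,,
age,,,,,,62.277,6.682,63.777,6.082,0.016
bmi,,,,,,25.855,3.819,25.514,3.871,0.225
pd,,,,,,19.436,14.616,14.612,13.696,4e-06
smoking,never,127,50.2,434,59.6,,,,,0.009
smoking,ever,126,49.8,294,40.4,,,,,
parity,,,,,,1.889,1.170,2.163,1.444,0.007
age_first_birth,,,,,,24.778,4.826,24.927,4.743,0.689
breastfeeding,never,7,3.8,37,6.1,,,,,0.227
breastfeeding,ever,179,96.2,537,93.9,,,,,
breastfeeding_duration,,,,,,10.234,6.750,11.663,10.341,0.089
diabetes,no,237,93.7,691,94.7,,,,,0.539
diabetes,yes,16,6.3,37,5.3,,,,,
age_menopause,,,,,,50.209,4.029,50.191,4.057,0.950
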