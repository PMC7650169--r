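component,field,sex,type,low,high,flag_value,condition_field,condition_value,points
age,age,male,band,0,57,,,,0
age,age,male,band,57,60,,,,1
age,age,male,band,60,63,,,,2
age,age,male,band,63,66,,,,3
age,age,male,band,66,69,,,,4
age,age,male,band,69,73,,,,5
age,age,male,band,73,76,,,,6
age,age,male,band,76,79,,,,7
age,age,male,band,79,82,,,,8
age,age,male,band,82,85,,,,9
age,age,male,band,85,Inf,,,,10
age,age,female,band,0,57,,,,0
age,age,female,band,57,60,,,,1
age,age,female,band,60,63,,,,2
age,age,female,band,63,65,,,,3
age,age,female,band,65,68,,,,4
age,age,female,band,68,71,,,,5
age,age,female,band,71,74,,,,6
age,age,female,band,74,77,,,,7
age,age,female,band,77,79,,,,8
age,age,female,band,79,82,,,,9
age,age,female,band,82,Inf,,,,10
systolic_bp,systolic_bp,male,band,0,106,,,,0
systolic_bp,systolic_bp,male,band,106,116,,,,1
systolic_bp,systolic_bp,male,band,116,126,,,,2
systolic_bp,systolic_bp,male,band,126,136,,,,3
systolic_bp,systolic_bp,male,band,136,146,,,,4
systolic_bp,systolic_bp,male,band,146,156,,,,5
systolic_bp,systolic_bp,male,band,156,166,,,,6
systolic_bp,systolic_bp,male,band,166,176,,,,7
systolic_bp,systolic_bp,male,band,176,186,,,,8
systolic_bp,systolic_bp,male,band,186,196,,,,9
systolic_bp,systolic_bp,male,band,196,Inf,,,,10
systolic_bp,systolic_bp,female,band,0,107,,,,0
systolic_bp,systolic_bp,female,band,107,119,,,,1
systolic_bp,systolic_bp,female,band,119,131,,,,2
systolic_bp,systolic_bp,female,band,131,144,,,,3
systolic_bp,systolic_bp,female,band,144,156,,,,4
systolic_bp,systolic_bp,female,band,156,168,,,,5
systolic_bp,systolic_bp,female,band,168,181,,,,6
systolic_bp,systolic_bp,female,band,181,193,,,,7
systolic_bp,systolic_bp,female,band,193,205,,,,8
systolic_bp,systolic_bp,female,band,205,Inf,,,,9
bp_treatment,bp_medication,both,flag,,,0,,,0
bp_treatment,bp_medication,both,flag,,,1,,,2
diabetes,diabetes,male,flag,,,0,,,0
diabetes,diabetes,male,flag,,,1,,,2
diabetes,diabetes,female,flag,,,0,,,0
diabetes,diabetes,female,flag,,,1,,,3
smoking,ever_smoked,both,flag,,,0,,,0
smoking,ever_smoked,both,flag,,,1,,,3
prior_cvd,prior_cvd,male,flag,,,0,,,0
prior_cvd,prior_cvd,male,flag,,,1,,,4
prior_cvd,prior_cvd,female,flag,,,0,,,0
prior_cvd,prior_cvd,female,flag,,,1,,,2
atrial_fibrillation,atrial_fibrillation,male,flag,,,0,,,0
atrial_fibrillation,atrial_fibrillation,male,flag,,,1,,,4
atrial_fibrillation,atrial_fibrillation,female,flag,,,0,,,0
atrial_fibrillation,atrial_fibrillation,female,flag,,,1,,,6
lvh,left_ventricular_hypertrophy,male,flag,,,0,,,0
lvh,left_ventricular_hypertrophy,male,flag,,,1,,,5
lvh,left_ventricular_hypertrophy,female,flag,,,0,,,0
lvh,left_ventricular_hypertrophy,female,flag,,,1,,,4
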