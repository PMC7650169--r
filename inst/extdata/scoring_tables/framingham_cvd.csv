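component,field,sex,type,low,high,flag_value,condition_field,condition_value,points
age,age,female,band,0,35,,,,0
age,age,female,band,35,40,,,,2
age,age,female,band,40,45,,,,4
age,age,female,band,45,50,,,,5
age,age,female,band,50,55,,,,7
age,age,female,band,55,60,,,,8
age,age,female,band,60,65,,,,9
age,age,female,band,65,70,,,,10
age,age,female,band,70,75,,,,11
age,age,female,band,75,Inf,,,,12
age,age,male,band,0,35,,,,0
age,age,male,band,35,40,,,,2
age,age,male,band,40,45,,,,5
age,age,male,band,45,50,,,,6
age,age,male,band,50,55,,,,8
age,age,male,band,55,60,,,,10
age,age,male,band,60,65,,,,11
age,age,male,band,65,70,,,,12
age,age,male,band,70,75,,,,14
age,age,male,band,75,Inf,,,,15
systolic_bp,systolic_bp,female,band,0,120,,bp_medication,0,-3
systolic_bp,systolic_bp,female,band,120,130,,bp_medication,0,0
systolic_bp,systolic_bp,female,band,130,140,,bp_medication,0,1
systolic_bp,systolic_bp,female,band,140,150,,bp_medication,0,2
systolic_bp,systolic_bp,female,band,150,160,,bp_medication,0,4
systolic_bp,systolic_bp,female,band,160,Inf,,bp_medication,0,5
systolic_bp,systolic_bp,female,band,0,120,,bp_medication,1,-1
systolic_bp,systolic_bp,female,band,120,130,,bp_medication,1,2
systolic_bp,systolic_bp,female,band,130,140,,bp_medication,1,3
systolic_bp,systolic_bp,female,band,140,150,,bp_medication,1,5
systolic_bp,systolic_bp,female,band,150,160,,bp_medication,1,6
systolic_bp,systolic_bp,female,band,160,Inf,,bp_medication,1,7
systolic_bp,systolic_bp,male,band,0,120,,bp_medication,0,-2
systolic_bp,systolic_bp,male,band,120,130,,bp_medication,0,0
systolic_bp,systolic_bp,male,band,130,140,,bp_medication,0,1
systolic_bp,systolic_bp,male,band,140,160,,bp_medication,0,2
systolic_bp,systolic_bp,male,band,160,Inf,,bp_medication,0,3
systolic_bp,systolic_bp,male,band,0,120,,bp_medication,1,0
systolic_bp,systolic_bp,male,band,120,130,,bp_medication,1,2
systolic_bp,systolic_bp,male,band,130,140,,bp_medication,1,3
systolic_bp,systolic_bp,male,band,140,160,,bp_medication,1,4
systolic_bp,systolic_bp,male,band,160,Inf,,bp_medication,1,5
smoking,ever_smoked,female,flag,,,0,,,0
smoking,ever_smoked,female,flag,,,1,,,3
smoking,ever_smoked,male,flag,,,0,,,0
smoking,ever_smoked,male,flag,,,1,,,4
diabetes,diabetes,female,flag,,,0,,,0
diabetes,diabetes,female,flag,,,1,,,4
diabetes,diabetes,male,flag,,,0,,,0
diabetes,diabetes,male,flag,,,1,,,3
cholesterol,high_cholesterol,female,flag,,,0,,,0
cholesterol,high_cholesterol,female,flag,,,1,,,4
cholesterol,high_cholesterol,male,flag,,,0,,,0
cholesterol,high_cholesterol,male,flag,,,1,,,3
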