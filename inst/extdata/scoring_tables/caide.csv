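component,field,sex,type,low,high,flag_value,condition_field,condition_value,points
age,age,both,band,0,47,,,,0
age,age,both,band,47,54,,,,3
age,age,both,band,54,Inf,,,,4
education,education_years,both,band,0,7,,,,3
education,education_years,both,band,7,10,,,,2
education,education_years,both,band,10,Inf,,,,0
sex,sex_female,both,flag,,,1,,,0
sex,sex_female,both,flag,,,0,,,1
systolic_bp,systolic_bp,both,band,0,141,,,,0
systolic_bp,systolic_bp,both,band,141,Inf,,,,2
bmi,bmi,both,band,0,30,,,,0
bmi,bmi,both,band,30,Inf,,,,2
cholesterol,high_cholesterol,both,flag,,,0,,,0
cholesterol,high_cholesterol,both,flag,,,1,,,2
physical_inactivity,physical_inactivity,both,flag,,,0,,,0
physical_inactivity,physical_inactivity,both,flag,,,1,,,1
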