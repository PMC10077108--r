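table,column,type,unit,description
baseline,subject_id,character,,unique subject identifier
baseline,country,character,,cohort/country label (grouping unit for the country random intercept)
baseline,age,numeric,years,age at baseline (18-75)
baseline,sex,integer,,0 = female; 1 = male
baseline,bmi,numeric,kg/m2,body-mass index
baseline,smoking_ever,integer,,1 = ever smoked
baseline,hba1c,numeric,mmol/mol,glycated hemoglobin A1c
baseline,hemoglobin,numeric,g/dL,blood hemoglobin
baseline,cholesterol,numeric,mg/dL,serum cholesterol
baseline,map,numeric,mm Hg,mean arterial pressure
baseline,log2_uacr,numeric,log2(mg/g),log2 urinary albumin-creatinine ratio
baseline,med_glucose,integer,,1 = on glucose-lowering medication
baseline,med_bp,integer,,1 = on blood-pressure-lowering medication
baseline,med_lipid,integer,,1 = on lipid-lowering medication
baseline,uacr,numeric,mg/g,urinary albumin-creatinine ratio (> 0)
baseline,baseline_egfr,numeric,mL/min/1.73m2,eGFR at the baseline visit (part of the outcome vector)
visits,subject_id,character,,unique subject identifier
visits,country,character,,cohort/country label
visits,time_since_baseline,numeric,years,time of the eGFR measurement since baseline (0 = baseline)
visits,egfr,numeric,mL/min/1.73m2,CKD-EPI 2021 estimated glomerular filtration rate
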