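surface_form,category,concept_id,concept_name,domain,vocabulary,standard
diabetes mellitus,Condition,201826,Type 2 diabetes mellitus,Condition,SNOMED,TRUE
diabetes,Condition,201820,Diabetes mellitus,Condition,SNOMED,TRUE
pregnancy,Condition,4299535,Pregnancy,Condition,SNOMED,TRUE
pregnant,Condition,4299535,Pregnancy,Condition,SNOMED,TRUE
hypertension,Condition,316866,Hypertensive disorder,Condition,SNOMED,TRUE
respiratory distress,Condition,4191650,Respiratory distress,Condition,SNOMED,TRUE
symptoms,Observation,4086121,Symptom,Observation,SNOMED,TRUE
symptomatic,Observation,4169095,Symptomatic,Observation,SNOMED,TRUE
sars-cov-2 diagnostic assay,Measurement,756055,SARS-CoV-2 diagnostic assay,Measurement,LOINC,TRUE
autoimmune disease,Condition,434621,Autoimmune disease,Condition,SNOMED,TRUE
thyroiditis,Condition,4185501,Thyroiditis,Condition,SNOMED,TRUE
melanoma,Condition,4162253,Malignant melanoma,Condition,SNOMED,TRUE
serum creatinine,Measurement,3016723,Creatinine serum/plasma,Measurement,LOINC,TRUE
hemoglobin,Measurement,3000963,Hemoglobin,Measurement,LOINC,TRUE
alanine aminotransferase,Measurement,3006923,Alanine aminotransferase,Measurement,LOINC,TRUE
ejection fraction,Measurement,3024653,Left ventricular ejection fraction,Measurement,LOINC,TRUE
metformin,Drug,1503297,Metformin,Drug,RxNorm,TRUE
insulin,Drug,21600713,Insulin,Drug,RxNorm,TRUE
warfarin,Drug,1310149,Warfarin,Drug,RxNorm,TRUE
chemotherapy,Procedure,4273629,Chemotherapy,Procedure,SNOMED,TRUE
leukapheresis,Procedure,4051330,Leukapheresis,Procedure,SNOMED,TRUE
dialysis,Procedure,4032243,Renal dialysis,Procedure,SNOMED,TRUE
mood,Condition,4183628,Mood finding,Condition,SNOMED,TRUE
mixed dementia,Condition,4043378,Mixed dementia,Condition,SNOMED,TRUE
female,Person_attribute,8532,Female,Person_attribute,Gender,TRUE
male,Person_attribute,8507,Male,Person_attribute,Gender,TRUE
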