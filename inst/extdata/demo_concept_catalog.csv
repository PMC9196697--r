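concept_id,concept_name,domain,vocabulary,standard,synonyms
201820,Diabetes mellitus,Condition,SNOMED,TRUE,diabetes
201826,Type 2 diabetes mellitus,Condition,SNOMED,TRUE,T2DM|adult onset diabetes
4299535,Pregnancy,Condition,SNOMED,TRUE,pregnant|gestation
316866,Hypertensive disorder,Condition,SNOMED,TRUE,hypertension|high blood pressure
4191650,Respiratory distress,Condition,SNOMED,TRUE,
4043378,Mixed dementia,Condition,SNOMED,TRUE,mixed type dementia
4182210,Dementia,Condition,SNOMED,TRUE,
80502,Osteoporosis,Condition,SNOMED,TRUE,
4229881,Liver finding,Condition,SNOMED,TRUE,liver dysfunction
198124,Kidney disease,Condition,SNOMED,TRUE,renal disease|kidney dysfunction
4137274,Caregiver,Observation,SNOMED,TRUE,carer
3016723,Creatinine serum/plasma,Measurement,LOINC,TRUE,serum creatinine
3000963,Hemoglobin,Measurement,LOINC,TRUE,
3006923,Alanine aminotransferase,Measurement,LOINC,TRUE,ALT|SGPT
1503297,Metformin,Drug,RxNorm,TRUE,
21600713,Insulin,Drug,RxNorm,TRUE,
1310149,Warfarin,Drug,RxNorm,TRUE,coumadin
4273629,Chemotherapy,Procedure,SNOMED,TRUE,chemo
4051330,Leukapheresis,Procedure,SNOMED,TRUE,
4032243,Renal dialysis,Procedure,SNOMED,TRUE,dialysis|hemodialysis
40481087,Mixed anxiety and depressive disorder,Condition,SNOMED,FALSE,mixed disorder
8532,Female,Person_attribute,Gender,TRUE,woman
8507,Male,Person_attribute,Gender,TRUE,man
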