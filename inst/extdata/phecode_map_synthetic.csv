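code,code_system,phecode,phenotype,category
401.1,ICD9CM,401.1,Essential hypertension,circulatory system
401.9,ICD9CM,401.1,Essential hypertension,circulatory system
I10,ICD10CM,401.1,Essential hypertension,circulatory system
402.90,ICD9CM,401.2,Hypertensive heart and/or renal disease,circulatory system
I11.9,ICD10CM,401.2,Hypertensive heart and/or renal disease,circulatory system
250.01,ICD9CM,250.1,Type 1 diabetes,endocrine/metabolic
250.11,ICD9CM,250.1,Type 1 diabetes,endocrine/metabolic
E10.9,ICD10CM,250.1,Type 1 diabetes,endocrine/metabolic
E10.65,ICD10CM,250.1,Type 1 diabetes,endocrine/metabolic
250.00,ICD9CM,250.2,Type 2 diabetes,endocrine/metabolic
250.02,ICD9CM,250.2,Type 2 diabetes,endocrine/metabolic
E11.9,ICD10CM,250.2,Type 2 diabetes,endocrine/metabolic
E11.65,ICD10CM,250.2,Type 2 diabetes,endocrine/metabolic
249.00,ICD9CM,249.1,Secondary diabetes mellitus,endocrine/metabolic
E08.9,ICD10CM,249.1,Secondary diabetes mellitus,endocrine/metabolic
585.9,ICD9CM,585.3,Chronic kidney disease,genitourinary
N18.3,ICD10CM,585.3,Chronic kidney disease,genitourinary
N18.9,ICD10CM,585.3,Chronic kidney disease,genitourinary
585.6,ICD9CM,585.3,Chronic kidney disease,genitourinary
586,ICD9CM,585.2,Chronic renal failure,genitourinary
N19,ICD10CM,585.2,Chronic renal failure,genitourinary
V42.0,ICD9CM,587.0,Kidney replaced by transplant,genitourinary
Z94.0,ICD10CM,587.0,Kidney replaced by transplant,genitourinary
593.9,ICD9CM,588.0,Other disorders of the kidney and ureters,genitourinary
N28.9,ICD10CM,588.0,Other disorders of the kidney and ureters,genitourinary
285.29,ICD9CM,285.2,Anemia of chronic disease,hematopoietic
D63.8,ICD10CM,285.2,Anemia of chronic disease,hematopoietic
288.50,ICD9CM,288.1,Decreased white blood cell count,hematopoietic
D72.819,ICD10CM,288.1,Decreased white blood cell count,hematopoietic
428.0,ICD9CM,428.1,Congestive heart failure NOS,circulatory system
I50.9,ICD10CM,428.1,Congestive heart failure NOS,circulatory system
464.00,ICD9CM,465.2,Acute laryngitis and tracheitis,respiratory
J04.2,ICD10CM,465.2,Acute laryngitis and tracheitis,respiratory
518.89,ICD9CM,509.8,Other diseases of lung,respiratory
J98.4,ICD10CM,509.8,Other diseases of lung,respiratory
573.8,ICD9CM,573.9,Other disorders of liver,digestive
K76.89,ICD10CM,573.9,Other disorders of liver,digestive
571.8,ICD9CM,571.5,Other chronic nonalcoholic liver disease,digestive
K76.0,ICD10CM,571.5,Other chronic nonalcoholic liver disease,digestive
276.1,ICD9CM,276.1,Hyposmolality,endocrine/metabolic
E87.1,ICD10CM,276.1,Hyposmolality,endocrine/metabolic
009.0,ICD9CM,008.5,Intestinal infection,infectious diseases
A09,ICD10CM,008.5,Intestinal infection,infectious diseases
628.9,ICD9CM,626.8,Infertility female,genitourinary
N97.9,ICD10CM,626.8,Infertility female,genitourinary
626.4,ICD9CM,626.2,Irregular menstrual cycle/bleeding,genitourinary
N92.6,ICD10CM,626.2,Irregular menstrual cycle/bleeding,genitourinary
789.00,ICD9CM,785.0,Abdominal pain,symptoms
R10.9,ICD10CM,785.0,Abdominal pain,symptoms
634.90,ICD9CM,634.0,Miscarriage stillbirth,pregnancy complications
O03.9,ICD10CM,634.0,Miscarriage stillbirth,pregnancy complications
719.40,ICD9CM,745.0,Pain in joint,musculoskeletal
M25.50,ICD10CM,745.0,Pain in joint,musculoskeletal
362.01,ICD9CM,250.7,Diabetic retinopathy,endocrine/metabolic
E11.319,ICD10CM,250.7,Diabetic retinopathy,endocrine/metabolic
530.81,ICD9CM,530.1,Gastroesophageal reflux disease,digestive
K21.9,ICD10CM,530.1,Gastroesophageal reflux disease,digestive
564.00,ICD9CM,563.0,Constipation,digestive
K59.00,ICD10CM,563.0,Constipation,digestive
311,ICD9CM,296.2,Depression,mental disorders
F32.9,ICD10CM,296.2,Depression,mental disorders
300.00,ICD9CM,300.1,Anxiety disorder,mental disorders
F41.9,ICD10CM,300.1,Anxiety disorder,mental disorders
493.90,ICD9CM,495.0,Asthma,respiratory
J45.909,ICD10CM,495.0,Asthma,respiratory
244.9,ICD9CM,244.4,Hypothyroidism,endocrine/metabolic
E03.9,ICD10CM,244.4,Hypothyroidism,endocrine/metabolic
280.9,ICD9CM,280.1,Iron deficiency anemia,hematopoietic
D50.9,ICD10CM,280.1,Iron deficiency anemia,hematopoietic
346.90,ICD9CM,340.0,Migraine,neurological
G43.909,ICD10CM,340.0,Migraine,neurological
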