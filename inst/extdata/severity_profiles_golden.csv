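phenotype_code,n_patients,prevalence,treatment_time,n_comorbidities,n_medications,n_procedures,cost
PHEN_A,2,0.666666666666667,5,1,1.5,1.5,60
PHEN_B,1,0.333333333333333,0,1,2,2,120
PHEN_C,2,0.666666666666667,5,0.5,0.5,1,5
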