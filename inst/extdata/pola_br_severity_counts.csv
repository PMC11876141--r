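variable,serious,non_serious,published_statistic,published_p,published_test,print_consistent
Male,225,473,5.39,0.020,pearson,TRUE
Female,129,367,NA,NA,NA,TRUE
Anaemia,26,26,10.633,0.001,pearson,TRUE
Febrile neutropenia,26,19,33.710,<0.001,pearson,FALSE
Thrombocytopenia,26,27,9.861,0.002,pearson,TRUE
Haematotoxicity,15,1,31.787,<0.001,pearson,TRUE
Leukopenia,12,5,13.777,<0.001,pearson,TRUE
Neutropenia,37,65,2.270,0.131,pearson,TRUE
Pancytopenia,31,23,3.706,0.054,pearson,FALSE
Cytopenia,14,17,3.630,0.057,pearson,TRUE
Myelosuppression,6,9,0.773,0.379,pearson,TRUE
Blood disorder,3,19,2.751,0.097,pearson,TRUE
Intestinal obstruction,0,16,NA,0.005,fisher,TRUE
Disease progression,202,662,35.809,<0.001,pearson,TRUE
Death,109,0,277.160,<0.001,pearson,TRUE
Pyrexia,40,9,65.371,<0.001,pearson,TRUE
General physical health deterioration,17,13,10.668,0.001,pearson,TRUE
Mucosal inflammation,14,3,22.841,<0.001,pearson,TRUE
Ill-defined disorder,7,28,1.607,0.205,pearson,TRUE
Oedema,3,7,NA,0.982,fisher,TRUE
Cytokine release syndrome,17,3,29.697,<0.001,pearson,TRUE
Immunosuppression,13,0,NA,<0.001,fisher,TRUE
COVID-19,79,79,34.687,<0.001,pearson,TRUE
Sepsis,32,15,34.220,<0.001,pearson,TRUE
Septic shock,28,2,59.353,<0.001,pearson,TRUE
Infection,17,19,5.430,0.020,pearson,TRUE
Bacterial infection,14,6,15.775,<0.001,pearson,TRUE
Fungal infection,12,8,8.921,0.003,pearson,TRUE
Urosepsis,11,9,6.221,0.013,pearson,TRUE
Candida infection,11,1,NA,<0.001,fisher,TRUE
Bacteraemia,11,0,NA,<0.001,fisher,TRUE
Tooth abscess,11,0,NA,<0.001,fisher,TRUE
Infected skin ulcer,10,0,NA,<0.001,fisher,TRUE
Cytomegalovirus infection,9,8,4.454,0.035,pearson,TRUE
COVID-19 pneumonia,7,3,NA,0.010,fisher,TRUE
Cytomegalovirus infection reactivation,2,37,11.546,<0.001,pearson,TRUE
Neutropenic sepsis,0,15,NA,0.008,fisher,TRUE
Neutropenic infection,0,14,NA,0.014,fisher,TRUE
Candida pneumonia,4,6,NA,0.495,fisher,TRUE
Varicella zoster virus infection,2,8,NA,0.732,fisher,TRUE
C-reactive protein increased,15,14,6.877,0.009,pearson,TRUE
Inflammatory marker increased,11,0,NA,<0.001,fisher,TRUE
Haemoglobin decreased,2,22,5.320,0.021,pearson,TRUE
Blood bilirubin increased,0,22,9.416,0.002,pearson,TRUE
Blood lactate dehydrogenase increased,48,124,0.291,0.590,pearson,TRUE
Aspartate aminotransferase increased,5,17,0.517,0.472,pearson,TRUE
Alanine aminotransferase increased,5,14,0.104,0.747,pearson,TRUE
Glomerular filtration rate decreased,1,12,NA,0.124,fisher,TRUE
Hypercalcaemia,11,10,5.254,0.022,pearson,TRUE
Neuropathy peripheral,14,13,6.468,0.011,pearson,TRUE
Confusional state,13,6,13.827,0.002,pearson,TRUE
Epilepsy,11,0,NA,<0.001,fisher,TRUE
Immune effector cell-associated neurotoxicity syndrome,11,0,NA,<0.001,fisher,TRUE
Polyneuropathy,0,12,NA,0.023,fisher,TRUE
Disturbance in attention,5,5,NA,0.173,fisher,TRUE
Neurotoxicity,2,15,2.643,0.104,pearson,TRUE
Renal failure,20,12,16.852,<0.001,pearson,TRUE
Respiratory failure,6,9,NA,0.399,fisher,TRUE
Deep vein thrombosis,1,19,5.911,0.015,pearson,TRUE
Haemorrhage,9,5,NA,0.007,fisher,TRUE
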