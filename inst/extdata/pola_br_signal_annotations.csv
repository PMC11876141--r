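soc,pt,n,ror025,deaths,medical_event,evidence,published_score,published_level
Blood and lymphatic system disorders,Neutropenia,102,7.19,20,IME,++,7,moderate
Blood and lymphatic system disorders,Pancytopenia,54,11.12,17,DME,++,8,high
Blood and lymphatic system disorders,Thrombocytopenia,53,4.90,10,IME,++,6,moderate
Blood and lymphatic system disorders,Anaemia,52,2.79,14,none,++,5,moderate
Blood and lymphatic system disorders,Febrile neutropenia,45,6.16,12,DME,++,7,moderate
Blood and lymphatic system disorders,Cytopenia,31,16.95,2,IME,+,5,moderate
Blood and lymphatic system disorders,Blood disorder,22,23.09,3,none,++,5,moderate
Blood and lymphatic system disorders,Leukopenia,17,2.68,3,IME,+,4,low
Blood and lymphatic system disorders,Haematotoxicity,16,13.23,0,none,++,5,moderate
Blood and lymphatic system disorders,Myelosuppression,15,3.15,0,IME,++,5,moderate
Gastrointestinal disorders,Intestinal obstruction,16,3.06,0,IME,+,4,low
General disorders and administration site conditions,Disease progression,864,193.80,120,none,-,5,moderate
General disorders and administration site conditions,Death,109,1.51,109,IME,-,4,low
General disorders and administration site conditions,Pyrexia,49,1.29,8,none,++,3,low
General disorders and administration site conditions,Ill-defined disorder,35,3.67,7,none,-,2,low
General disorders and administration site conditions,General physical health deterioration,30,2.20,8,none,+,3,low
General disorders and administration site conditions,Mucosal inflammation,17,5.40,0,none,+,4,low
General disorders and administration site conditions,Oedema,10,1.46,3,none,++,3,low
Immune system disorders,Cytokine release syndrome,20,6.94,0,IME,+,5,moderate
Immune system disorders,Immunosuppression,13,9.23,1,IME,+,5,moderate
Infections and infestations,COVID-19,158,4.59,47,none,+,4,low
Infections and infestations,Sepsis,47,4.26,16,IME,++,5,moderate
Infections and infestations,Cytomegalovirus infection reactivation,39,59.04,2,IME,+,5,moderate
Infections and infestations,Infection,36,2.00,12,none,++,4,low
Infections and infestations,Septic shock,30,6.56,15,IME,++,6,moderate
Infections and infestations,Urosepsis,20,16.94,11,IME,+,5,moderate
Infections and infestations,Bacterial infection,20,8.26,14,none,+,4,low
Infections and infestations,Fungal infection,20,4.69,2,none,+,3,low
Infections and infestations,Cytomegalovirus infection,17,7.47,2,IME,+,5,moderate
Infections and infestations,Neutropenic sepsis,15,15.56,0,DME,++,7,moderate
Infections and infestations,Neutropenic infection,14,150.77,0,DME,++,7,moderate
Infections and infestations,Candida infection,12,4.01,8,none,+,3,low
Infections and infestations,Bacteraemia,11,6.26,11,IME,+,5,moderate
Infections and infestations,Tooth abscess,11,6.66,0,IME,+,5,moderate
Infections and infestations,COVID-19 pneumonia,10,2.42,7,IME,++,5,moderate
Infections and infestations,Candida pneumonia,10,223.88,0,IME,+,5,moderate
Infections and infestations,Infected skin ulcer,10,36.23,0,none,+,4,low
Infections and infestations,Varicella zoster virus infection,10,24.79,1,none,+,4,low
Investigations,Blood lactate dehydrogenase increased,172,165.00,36,none,+,5,moderate
Investigations,C-reactive protein increased,29,4.92,8,none,+,3,low
Investigations,Haemoglobin decreased,24,1.98,0,none,++,3,low
Investigations,Aspartate aminotransferase increased,22,4.15,5,none,++,4,low
Investigations,Blood bilirubin increased,22,8.81,0,none,-,3,low
Investigations,Alanine aminotransferase increased,19,2.84,5,none,++,4,low
Investigations,Glomerular filtration rate decreased,13,6.61,1,none,+,4,low
Investigations,Inflammatory marker increased,11,10.75,0,none,+,4,low
Metabolism and nutrition disorders,Hypercalcaemia,21,13.38,5,none,+,4,low
Nervous system disorders,Neuropathy peripheral,27,2.21,7,IME,++,5,moderate
Nervous system disorders,Confusional state,19,1.07,8,none,+,2,low
Nervous system disorders,Neurotoxicity,17,6.69,0,IME,++,6,moderate
Nervous system disorders,Polyneuropathy,12,6.11,0,IME,+,5,moderate
Nervous system disorders,Immune effector cell-associated neurotoxicity syndrome,11,14.03,1,IME,+,5,moderate
Nervous system disorders,Epilepsy,11,2.78,0,IME,+,4,low
Nervous system disorders,Disturbance in attention,10,1.49,5,none,+,2,low
Renal and urinary disorders,Renal failure,32,1.62,12,DME,+,4,low
"Respiratory, thoracic and mediastinal disorders",Respiratory failure,15,1.90,2,IME,+,3,low
Vascular disorders,Deep vein thrombosis,20,4.07,1,IME,+,4,low
Vascular disorders,Haemorrhage,14,1.02,5,IME,++,4,low
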