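Bacteraemia
Candida pneumonia
COVID-19 pneumonia
Cytokine release syndrome
Cytomegalovirus infection
Cytomegalovirus infection reactivation
Cytopenia
Death
Deep vein thrombosis
Epilepsy
Haemorrhage
Immune effector cell-associated neurotoxicity syndrome
Immunosuppression
Intestinal obstruction
Leukopenia
Myelosuppression
Neuropathy peripheral
Neurotoxicity
Neutropenia
Polyneuropathy
Respiratory failure
Sepsis
Septic shock
Thrombocytopenia
Tooth abscess
Urosepsis
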