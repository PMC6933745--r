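{
  "diabetes": "NCD",
  "hypertension": "NCD",
  "heart_disease": "NCD",
  "stroke": "NCD",
  "cancer": "NCD",
  "copd": "NCD",
  "asthma": "NCD",
  "arthritis": "NCD",
  "chronic_kidney": "NCD",
  "neuro_psychiatric": "NCD",
  "tuberculosis": "CD",
  "malaria": "CD",
  "diarrhoea": "CD",
  "respiratory_infection": "CD",
  "typhoid": "CD",
  "hepatitis": "CD",
  "skin_infection": "CD",
  "infectious_fever": "CD",
  "injury": "OD",
  "pregnancy_related": "OD",
  "newborn_illness": "OD",
  "undiagnosed_fever": "OD"
}
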