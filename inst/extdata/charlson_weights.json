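{
  "charlson": {
    "myocardial_infarction": [1],
    "congestive_heart_failure": [1],
    "peripheral_vascular_disease": [1],
    "cerebrovascular_disease": [1],
    "dementia": [1],
    "chronic_pulmonary_disease": [1],
    "rheumatic_disease": [1],
    "peptic_ulcer_disease": [1],
    "mild_liver_disease": [1],
    "diabetes_without_complications": [1],
    "diabetes_with_complications": [2],
    "hemiplegia_paraplegia": [2],
    "renal_disease": [2],
    "any_malignancy": [2],
    "moderate_severe_liver_disease": [3],
    "metastatic_solid_tumor": [6],
    "aids_hiv": [6]
  },
  "quan": {
    "myocardial_infarction": [0],
    "congestive_heart_failure": [2],
    "peripheral_vascular_disease": [0],
    "cerebrovascular_disease": [0],
    "dementia": [2],
    "chronic_pulmonary_disease": [1],
    "rheumatic_disease": [1],
    "peptic_ulcer_disease": [0],
    "mild_liver_disease": [2],
    "diabetes_without_complications": [0],
    "diabetes_with_complications": [1],
    "hemiplegia_paraplegia": [2],
    "renal_disease": [1],
    "any_malignancy": [2],
    "moderate_severe_liver_disease": [4],
    "metastatic_solid_tumor": [6],
    "aids_hiv": [4]
  },
  "hierarchy": [
    ["metastatic_solid_tumor", "any_malignancy"],
    ["moderate_severe_liver_disease", "mild_liver_disease"],
    ["diabetes_with_complications", "diabetes_without_complications"]
  ]
}
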