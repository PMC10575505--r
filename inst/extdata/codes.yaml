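# Diagnosis and medication code configuration.
# ICD-9 entries may be single codes (exact match) or "480-481" style ranges
# (match on 3-digit stem); condition code lists match by prefix; medication
# classes match dispensation records by ATC prefix.
cap_codes:
  ICD9: ["480-481"]
  OHIP: ["486", "986"]
conditions:
  diabetes:
    ICD9: ["250"]
    ICD10: ["E10", "E11", "E13", "E14"]
  congestive_heart_failure:
    ICD9: ["428"]
    ICD10: ["I50"]
  myocardial_infarction:
    ICD9: ["410", "412"]
    ICD10: ["I21", "I22"]
  copd:
    ICD9: ["491", "492", "496"]
    ICD10: ["J43", "J44"]
  asthma:
    ICD9: ["493"]
    ICD10: ["J45"]
  coronary_artery_disease:
    ICD9: ["414"]
    ICD10: ["I25"]
  hypertension:
    ICD9: ["401", "402"]
    ICD10: ["I10", "I11"]
  cancer:
    ICD9: ["140-208"]
    ICD10: ["C"]
  chronic_kidney_disease:
    ICD9: ["585"]
    ICD10: ["N18"]
medication_classes:
  immunosuppressive_meds:
    ATC: ["L04A", "H02AB", "L01"]   # anti-rejection / anti-rheumatic, oral glucocorticoids, chemotherapy
  interacting_drugs:
    ATC: ["B01AA"]                  # vitamin K antagonists
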