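# SYNTHETIC example condition dictionary.
#
# Maps condition names to ICD-9 code patterns (exact codes or prefix
# wildcards; "303.*" matches 303, 303.9, 303.90, ...). The code families
# below are illustrative groupings for demonstration and testing only --
# they are NOT a clinically validated comorbidity code set and must not be
# used to define conditions in real analyses.
alcohol_abuse:
  - "303.*"
  - "305.0*"
drug_abuse:
  - "304.*"
  - "305.2*"
  - "305.3*"
  - "305.4*"
  - "305.5*"
  - "305.6*"
  - "305.7*"
depression:
  - "296.2*"
  - "296.3*"
  - "311"
anxiety:
  - "300.0*"
  - "300.2*"
ptsd:
  - "309.81"
hypertension:
  - "401.*"
  - "402.*"
  - "403.*"
  - "404.*"
coronary_artery_disease:
  - "414.0*"
  - "414.8"
  - "414.9"
congestive_heart_failure:
  - "428.*"
diabetes:
  - "250.*"
chronic_renal_failure:
  - "585.*"
liver_disease:
  - "571.*"
chronic_hepatitis:
  - "070.32"
  - "070.54"
chronic_pulmonary_disease:
  - "490"
  - "491.*"
  - "492.*"
  - "496"
chronic_pain:
  - "338.2*"
  - "338.4"
malignant_neoplasm:
  - "153.*"
  - "162.*"
  - "174.*"
  - "185"
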