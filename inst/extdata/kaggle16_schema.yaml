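schema_id: kaggle16
feature_names:
- age
- gender
- chest_pain_type
- blood_pressure
- cholesterol
- max_heart_rate
- exercise_angina
- plasma_glucose
- skin_thickness
- insulin
- bmi
- diabetes_pedigree
- hypertension
- heart_disease
- residence_type
- smoking_status
categorical:
- residence_type
- smoking_status
label_column: triage
mandatory: gender
levels:
  residence_type:
  - Rural
  - Urban
  smoking_status:
  - Unknown
  - never smoked
  - previously smoked
  - smoke
  triage:
  - Green
  - Orange
  - Red
  - Yellow
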