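{
  "sex": "Male",
  "age": 34,
  "weight": 85,
  "height": 186,
  "neck_circumference": 46,
  "smoker": "no",
  "cigarettes_per_day": 0,
  "years_smoking": 0,
  "drinking": "occasional",
  "grams_alcohol": 0,
  "hypertension": 0,
  "resistant_hypertension": 0,
  "acva": 0,
  "acva_past_year": 0,
  "diabetes": 0,
  "ischemic_heart_disease": 0,
  "copd": 0,
  "home_oxygen": 0,
  "rhinitis": 0,
  "depression": 0,
  "atrial_fibrillation": 0,
  "heart_failure": 0,
  "benzodiazepines": 0,
  "antidepressants": 0,
  "neuroleptics": 0,
  "antihistamines": 0,
  "morphics": 0,
  "hypnotics": 0,
  "hours_of_sleep": 7,
  "minutes_to_sleep": 20,
  "prolonged_awakenings": "Often",
  "unrefreshing_sleep": "No",
  "daytime_tiredness": "No",
  "morning_dullness": "Occasionally",
  "unjustified_multiple_awakenings": "No",
  "nocturia": "Often",
  "breathless_awakenings": "No",
  "reported_apneas": "Often",
  "snorer": "Yes",
  "high_intensity_snorer": "Yes",
  "snore_awakenings": "Occasionally",
  "ahi": 11.9
}
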