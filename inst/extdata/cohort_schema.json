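{
  "format": "CSV, comma-separated, UTF-8, '.' decimal separator, header row",
  "boolean_encoding": "0/1 on write; 0,1,true,false,yes,no accepted case-insensitively on read",
  "missing_encoding": "empty cell",
  "mandatory_columns": {
    "participant_id": {"type": "string", "unique": true},
    "sbp": {"type": "number", "unit": "mmHg", "constraint": "> dbp > 0"},
    "dbp": {"type": "number", "unit": "mmHg", "constraint": "> 0"},
    "self_reported_hypertension": {"type": "boolean"},
    "diabetes": {"type": "boolean"},
    "ami": {"type": "boolean"},
    "angina": {"type": "boolean"},
    "other_ihd": {"type": "boolean"},
    "stroke_tia": {"type": "boolean"},
    "pulm_heart": {"type": "boolean"},
    "rheum_heart": {"type": "boolean"},
    "tuberculosis": {"type": "boolean"},
    "emphysema": {"type": "boolean"},
    "chronic_bronchitis": {"type": "boolean"},
    "copd": {"type": "boolean"},
    "asthma": {"type": "boolean"},
    "hepatitis_cirrhosis": {"type": "boolean"},
    "peptic_ulcer": {"type": "boolean"},
    "gallstones": {"type": "boolean"},
    "ckd": {"type": "boolean"},
    "osteoporosis": {"type": "boolean"},
    "fracture": {"type": "boolean"},
    "rheumatoid_arthritis": {"type": "boolean"},
    "depression": {"type": "boolean"},
    "anxiety": {"type": "boolean"},
    "neurasthenia": {"type": "boolean"},
    "other_mental": {"type": "boolean"},
    "brain_injury": {"type": "boolean"},
    "cancer": {"type": "boolean"},
    "sex": {"type": "categorical", "levels": ["male", "female"]},
    "age": {"type": "number", "unit": "years", "nominal_range": [35, 74]}
  },
  "optional_columns": {
    "province": {"type": "categorical", "levels": ["shaanxi", "xinjiang", "ningxia", "gansu", "qinghai"]},
    "urbanicity": {"type": "categorical", "levels": ["rural", "urban"]},
    "ethnicity": {"type": "categorical", "levels": ["han", "uygur", "kazak", "hui", "tibetan", "other"]},
    "education": {"type": "categorical", "levels": ["no_formal", "primary", "middle", "college"]},
    "occupation": {"type": "categorical", "levels": ["unemployed", "agriculture", "employed"]},
    "marital": {"type": "categorical", "levels": ["married", "widowed", "separated_divorced", "never_married"]},
    "wealth_tertile": {"type": "integer", "levels": [1, 2, 3]},
    "smoking": {"type": "categorical", "levels": ["never", "former", "current"]},
    "drinking": {"type": "categorical", "levels": ["never", "occasional", "usual"]},
    "pa_tertile": {"type": "categorical", "levels": ["low", "moderate", "high"]},
    "sleep_hours": {"type": "number", "unit": "hours", "constraint": ">= 0"},
    "height_cm": {"type": "number", "unit": "cm", "constraint": "> 0"},
    "weight_kg": {"type": "number", "unit": "kg", "constraint": "> 0"},
    "waist_cm": {"type": "number", "unit": "cm", "constraint": "> 0"}
  },
  "notes": [
    "Hypertension is not a column: final hypertension status is derived from sbp/dbp/self_reported_hypertension under a named criterion.",
    "Disease-flag columns may appear in any order in the file; registry order is imposed on read."
  ]
}
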