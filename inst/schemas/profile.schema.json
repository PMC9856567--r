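{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "lynchRisk user profile",
  "type": "object",
  "required": ["gene", "sex", "current_age", "height", "weight"],
  "properties": {
    "gene": {"enum": ["MLH1", "MSH2", "MSH6", "PMS2", "EPCAM"]},
    "sex": {"enum": ["male", "female"]},
    "current_age": {"type": "integer", "minimum": 1, "maximum": 84},
    "race": {"enum": ["All_Races", "AIAN", "API", "Black", "White"]},
    "ethnicity": {"enum": ["All_Ethnicities", "Hispanic", "Non_Hispanic"]},
    "height": {
      "type": "object",
      "required": ["value", "unit"],
      "properties": {
        "value": {"type": "number", "exclusiveMinimum": 0},
        "unit": {"enum": ["m", "cm", "in"]}
      }
    },
    "weight": {
      "type": "object",
      "required": ["value", "unit"],
      "properties": {
        "value": {"type": "number", "exclusiveMinimum": 0},
        "unit": {"enum": ["kg", "lb"]}
      }
    },
    "prior_cancers": {
      "type": "array",
      "items": {"enum": ["brain", "colorectal", "endometrial", "gastric",
                         "ovarian", "pancreatic", "prostate",
                         "small_intestine", "urinary_bladder"]}
    },
    "hysterectomy_done": {"type": "boolean"},
    "oophorectomy_done": {"type": "boolean"}
  }
}
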