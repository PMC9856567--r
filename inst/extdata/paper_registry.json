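{
  "schema_version": "registry/1",
  "constants": {
    "colonoscopy_adherence_p": 0.818,
    "lifetime_cap": 0.90,
    "ref_bmi_male": 27.1,
    "ref_bmi_female": 26.0,
    "bmi_clamp_low": 25,
    "bmi_clamp_high": 30,
    "max_weight_loss_bmi_points": 5,
    "personograph_icons": 20,
    "display_rounding_pct": 1
  },
  "interventions": [
    {
      "id": "colonoscopy",
      "cancer": "colorectal",
      "measure_kind": "RR",
      "application": "binary",
      "value": 0.44,
      "applicable_genes": ["MLH1", "MSH2"],
      "generalized_genes": ["MLH1", "MSH2", "MSH6", "PMS2", "EPCAM"],
      "note": "Estimate assumes colonoscopic screening every 3 years; your clinician may recommend a different frequency."
    },
    {
      "id": "aspirin",
      "cancer": "colorectal",
      "measure_kind": "HR",
      "application": "binary",
      "schedule": [[2, 0.56], [5, 0.63], [10, 0.65]],
      "applicable_genes": ["MLH1", "MSH2", "MSH6"],
      "generalized_genes": ["MLH1", "MSH2", "MSH6", "PMS2", "EPCAM"],
      "note": "Estimate assumes a 600 mg daily aspirin dose; your clinician may recommend a different dosage or no aspirin at all."
    },
    {
      "id": "weight_change",
      "cancer": "colorectal",
      "measure_kind": "HR",
      "application": "continuous",
      "per_step_value": 0.07,
      "step_unit": "bmi_point",
      "applicable_genes": ["MLH1"],
      "generalized_genes": ["MLH1"],
      "note": "Hazard ratio changes by 7% per BMI point; the source study covered MLH1 carriers only."
    },
    {
      "id": "weight_change",
      "cancer": "endometrial",
      "measure_kind": "OR",
      "application": "continuous",
      "per_step_value": 0.20,
      "step_unit": "kg5",
      "applicable_genes": [],
      "generalized_genes": ["MLH1", "MSH2", "MSH6"],
      "note": "Odds ratio changes by 20% per 5 kg of body weight; the source study was of the general population, extended to carriers by assumption."
    },
    {
      "id": "hysterectomy",
      "cancer": "endometrial",
      "measure_kind": "ZERO",
      "application": "binary",
      "value": 0,
      "applicable_genes": ["MLH1", "MSH2", "MSH6"],
      "generalized_genes": ["MLH1", "MSH2", "MSH6"],
      "note": "Prophylactic hysterectomy is assumed to remove endometrial cancer risk entirely."
    },
    {
      "id": "oophorectomy",
      "cancer": "ovarian",
      "measure_kind": "ZERO",
      "application": "binary",
      "value": 0,
      "applicable_genes": ["MLH1", "MSH2", "MSH6"],
      "generalized_genes": ["MLH1", "MSH2", "MSH6", "PMS2"],
      "note": "Prophylactic salpingo-oophorectomy is assumed to remove ovarian cancer risk entirely."
    }
  ]
}
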