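{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "lynchRisk intervention registry",
  "type": "object",
  "required": ["constants", "interventions"],
  "properties": {
    "schema_version": {"type": "string"},
    "constants": {
      "type": "object",
      "required": ["colonoscopy_adherence_p", "lifetime_cap", "ref_bmi_male",
                   "ref_bmi_female", "bmi_clamp_low", "bmi_clamp_high",
                   "max_weight_loss_bmi_points", "personograph_icons",
                   "display_rounding_pct"],
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    },
    "interventions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "cancer", "measure_kind", "application",
                     "generalized_genes"],
        "properties": {
          "id": {"enum": ["colonoscopy", "aspirin", "weight_change",
                          "hysterectomy", "oophorectomy"]},
          "cancer": {"type": "string"},
          "measure_kind": {"enum": ["RR", "OR", "HR", "ZERO"]},
          "application": {"enum": ["binary", "continuous"]},
          "value": {"type": "number", "minimum": 0},
          "per_step_value": {"type": "number", "exclusiveMinimum": -1},
          "step_unit": {"enum": ["bmi_point", "kg5"]},
          "schedule": {
            "type": "array",
            "items": {
              "type": "array",
              "prefixItems": [{"type": "number", "minimum": 0},
                              {"type": "number", "exclusiveMinimum": 0}],
              "minItems": 2, "maxItems": 2
            }
          },
          "applicable_genes": {"type": "array", "items": {"type": "string"}},
          "generalized_genes": {"type": "array", "items": {"type": "string"}},
          "note": {"type": "string"}
        }
      }
    }
  }
}
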