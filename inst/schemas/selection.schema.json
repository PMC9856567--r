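{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "lynchRisk intervention selection",
  "type": "object",
  "properties": {
    "colonoscopy": {"type": "boolean"},
    "aspirin": {"type": "boolean"},
    "weight_loss_lb": {"type": "integer", "minimum": 0},
    "hysterectomy": {"type": "boolean"},
    "oophorectomy": {"type": "boolean"}
  }
}
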