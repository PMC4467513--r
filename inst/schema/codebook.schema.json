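{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "VA codebook",
  "type": "object",
  "required": ["items"],
  "properties": {
    "items": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "kind": {"enum": ["binary", "count", "duration_days", "categorical"]},
          "allowed_values": {"type": "array", "items": {"type": "string"}},
          "missing_codes": {"type": "array", "items": {"type": "string"}},
          "label": {"type": "string"}
        },
        "additionalProperties": false
      }
    }
  },
  "additionalProperties": false
}
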