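{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "VA hierarchy config",
  "type": "object",
  "properties": {
    "allow_order_override": {"type": "boolean"},
    "neonate": {"$ref": "#/$defs/hierarchy"},
    "child": {"$ref": "#/$defs/hierarchy"}
  },
  "additionalProperties": false,
  "$defs": {
    "hierarchy": {
      "type": "object",
      "required": ["ordered_causes"],
      "properties": {
        "ordered_causes": {
          "type": "array", "minItems": 1,
          "items": {"type": "string"}, "uniqueItems": true
        },
        "multi_cause_group": {
          "type": "array", "items": {"type": "string"}
        },
        "fallback_cause": {"type": "string"}
      },
      "additionalProperties": false
    }
  }
}
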