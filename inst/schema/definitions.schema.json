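{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "VA case-definition config",
  "type": "object",
  "properties": {
    "parameters": {
      "type": "object",
      "properties": {
        "min_stools_per_day": {"type": "number", "minimum": 0},
        "chronic_days_min": {"type": "number", "minimum": 0},
        "aids_resp_min_days": {"type": "number", "minimum": 0},
        "aids_resp_max_days": {"type": "number", "minimum": 0},
        "diarrhea_symptom_only": {"type": "boolean"}
      },
      "additionalProperties": false
    },
    "definitions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["cause", "predicate"],
        "properties": {
          "cause": {"type": "string", "minLength": 1},
          "strata": {
            "type": "array",
            "items": {"enum": ["neonate", "child"]},
            "minItems": 1
          },
          "reconstructed": {"type": "boolean"},
          "predicate": {"$ref": "#/$defs/predicate"}
        },
        "additionalProperties": false
      }
    }
  },
  "additionalProperties": false,
  "$defs": {
    "predicate": {
      "type": "object",
      "minProperties": 1,
      "maxProperties": 1,
      "properties": {
        "item_equals": {
          "type": "object",
          "required": ["item"],
          "properties": {
            "item": {"type": "string"},
            "value": {"type": "string"}
          },
          "additionalProperties": false
        },
        "item_at_least": {
          "type": "object",
          "required": ["item", "min_count"],
          "properties": {
            "item": {"type": "string"},
            "min_count": {"type": "number", "minimum": 0}
          },
          "additionalProperties": false
        },
        "duration_in_days": {
          "type": "object",
          "required": ["item", "min_days"],
          "properties": {
            "item": {"type": "string"},
            "min_days": {"type": "number", "minimum": 0},
            "max_days": {
              "anyOf": [{"type": "number"}, {"const": ".inf"}]
            }
          },
          "additionalProperties": false
        },
        "all_of": {"type": "array", "minItems": 1,
                   "items": {"$ref": "#/$defs/predicate"}},
        "any_of": {"type": "array", "minItems": 1,
                   "items": {"$ref": "#/$defs/predicate"}},
        "none_of": {"type": "array", "minItems": 1,
                    "items": {"$ref": "#/$defs/predicate"}}
      },
      "additionalProperties": false
    }
  }
}
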