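{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pharmnetrisk rubric configuration",
  "type": "object",
  "required": ["dimensions"],
  "properties": {
    "dimensions": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "label", "group", "sub_rules", "max_points"],
        "properties": {
          "id": {"type": "string"},
          "label": {"type": "string"},
          "group": {"enum": ["intrinsic", "extrinsic", "counterfeit"]},
          "max_points": {"type": "integer", "minimum": 0},
          "sub_rules": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "label", "answer_kind", "fields",
                           "max_points"],
              "properties": {
                "id": {"type": "string"},
                "label": {"type": "string"},
                "answer_kind": {
                  "enum": ["binary", "banded_count", "enumerated"]
                },
                "fields": {
                  "oneOf": [
                    {"type": "string"},
                    {"type": "array", "items": {"type": "string"}}
                  ]
                },
                "point_map": {
                  "type": "object",
                  "additionalProperties": {"type": "integer", "minimum": 0}
                },
                "bands": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["min", "points"],
                    "properties": {
                      "min": {"type": "integer", "minimum": 0},
                      "max": {"type": ["integer", "null"]},
                      "points": {"type": "integer", "minimum": 0}
                    }
                  }
                },
                "max_points": {"type": "integer", "minimum": 0}
              }
            }
          }
        }
      }
    },
    "override_score": {"type": "integer", "minimum": 0, "default": 15},
    "weighted_divisor": {"type": "number", "exclusiveMinimum": 0,
                         "default": 10},
    "severity_bands": {
      "type": "object",
      "properties": {
        "low_max": {"type": "number", "default": 0.25},
        "high_min": {"type": "number", "default": 0.75}
      }
    },
    "theoretical_max": {"type": "integer", "default": 15}
  }
}
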