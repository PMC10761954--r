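{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "racekin/system-config/v1",
  "title": "Transaminase reaction-system configuration",
  "type": "object",
  "required": ["compounds", "reactions", "enzyme"],
  "properties": {
    "units": {
      "type": "object",
      "properties": {
        "concentration": {"enum": ["mM", "uM", "µM", "M"]},
        "time": {"enum": ["h", "hr", "hour", "min", "s"]}
      }
    },
    "compounds": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "amine_S": {"type": "string"},
          "amine_R": {"type": "string"},
          "ketone": {"type": "string"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "donor", "ketone", "k_OD", "k_RA"],
        "properties": {
          "label": {"type": "string"},
          "donor": {"type": "string"},
          "ketone": {"type": "string"},
          "k_OD": {"type": "number", "minimum": 0},
          "k_RA": {"type": "number", "minimum": 0}
        }
      }
    },
    "enzyme": {
      "type": "object",
      "required": ["total"],
      "properties": {
        "total": {"type": "number", "exclusiveMinimum": 0},
        "initial_E_PLP_fraction": {
          "type": "number", "minimum": 0, "maximum": 1
        }
      }
    },
    "initial_concentrations": {
      "type": "object",
      "additionalProperties": {"type": "number", "minimum": 0}
    }
  }
}
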