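{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "racekin/geometry-report/v1",
  "title": "NAT geometry report for one docking pose",
  "type": "object",
  "required": ["d_NAT", "theta_BD", "theta_DH", "d_Halpha_Neps",
               "halpha_same_face", "verdict", "reasons"],
  "properties": {
    "d_NAT": {"type": "number", "exclusiveMinimum": 0},
    "theta_BD": {"type": "number", "minimum": 0, "maximum": 180},
    "theta_DH": {"type": "number", "minimum": 0, "maximum": 180},
    "d_Halpha_Neps": {"type": "number", "exclusiveMinimum": 0},
    "halpha_same_face": {"type": "boolean"},
    "verdict": {"enum": ["productive", "nonproductive"]},
    "reasons": {"type": "array", "items": {"type": "string"}}
  }
}
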