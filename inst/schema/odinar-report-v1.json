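{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "odinar-report-v1",
  "title": "odinar CLI report",
  "type": "object",
  "required": ["schema", "config"],
  "properties": {
    "schema": {"const": "odinar-report-v1"},
    "config": {
      "type": "object",
      "required": ["command", "seed"],
      "properties": {
        "command": {"enum": ["simulate", "fit", "test", "study"]},
        "seed": {"type": "integer"},
        "phi": {"type": ["array", "string"]},
        "innovation": {"enum": ["poisson", "geometric"]},
        "T": {"type": "integer"},
        "reps": {"type": "integer"}
      }
    },
    "fits": {"type": "object"},
    "el_tests": {"type": "array"},
    "h_region": {"type": "object"},
    "table": {"type": "string"},
    "best_bic": {"type": ["string", "null"]}
  }
}
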