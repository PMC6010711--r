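{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "popcompare describe report",
  "type": "object",
  "required": ["type", "seed", "n_reps", "stages", "populations"],
  "properties": {
    "type": { "const": "describe" },
    "seed": { "type": "integer" },
    "n_reps": { "type": "integer" },
    "stages": { "type": "array", "items": { "type": "string" } },
    "populations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["population_id", "n", "lambda", "R0", "sss", "rv",
                     "history_composition", "intervals", "sss_distance"],
        "properties": {
          "population_id": { "type": "string" },
          "n": { "type": "integer" },
          "lambda": { "type": "number" },
          "R0": { "type": "number" },
          "T": { "type": ["number", "null"] },
          "T_undefined_reason": { "type": ["string", "null"] },
          "sss": { "type": "array", "items": { "type": "number" } },
          "rv": { "type": "array", "items": { "type": "number" } },
          "sensitivity": { "type": "array" },
          "elasticity": { "type": "array" },
          "history_composition": { "type": "object" },
          "intervals": { "type": "object" },
          "sss_distance": { "type": "object" }
        }
      }
    }
  }
}
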