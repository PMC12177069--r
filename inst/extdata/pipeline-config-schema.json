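{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "stimgait pipeline configuration",
  "type": "object",
  "properties": {
    "cohort": {
      "type": "object",
      "properties": {
        "n_subjects": {"type": "integer", "minimum": 1, "maximum": 3,
          "description": "Subjects drawn from the example implant pattern (bilateral, bilateral, unilateral)"},
        "n_visits": {"type": "integer", "minimum": 1},
        "n_settings": {"type": "integer", "minimum": 2,
          "description": "Settings per visit including the clinical setting"},
        "n_strides": {"type": "integer", "minimum": 4,
          "description": "Gait cycles per reference side per trial"},
        "turn_every": {"type": "number",
          "description": "Turning stride interval (walkway loop geometry)"},
        "neural": {"type": "boolean"}
      }
    },
    "stages": {
      "type": "array",
      "items": {"enum": ["simulate", "gait", "wpi", "spectral", "optimize", "stats"]}
    },
    "spectral": {
      "type": "object",
      "properties": {
        "sites": {"type": "array", "items": {"enum": ["GP", "ctxA", "ctxB"]}},
        "pairs": {"type": "array",
          "items": {"enum": ["GP-ctxA", "GP-ctxB", "ctxA-ctxB"]}},
        "bands": {"type": "array",
          "items": {"enum": ["delta", "theta", "alpha", "beta"]}},
        "fmin": {"type": "number", "minimum": 0.5},
        "fmax": {"type": "number", "maximum": 250}
      }
    },
    "gpr": {
      "type": "object",
      "properties": {
        "budget": {"type": "integer", "minimum": 3,
          "description": "Total oracle evaluations in the optimization loop"},
        "restarts": {"type": "integer", "minimum": 1}
      }
    },
    "feedback": {
      "type": "object",
      "properties": {
        "concordance": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "seed": {"type": "integer",
      "description": "Master seed; every stage derives a recorded sub-seed"}
  }
}
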