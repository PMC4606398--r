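{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "acsmarkov parameter file",
  "description": "Parameter set for the two-component decision model (one-year decision tree + eight-state Markov cohort model) comparing adjunctive CHM plus conventional treatment with conventional treatment alone after PCI. YAML files conforming to this schema are read by acsmarkov::read_parameters().",
  "type": "object",
  "required": ["chm_arm", "conv_arm", "long_term", "utilities"],
  "$defs": {
    "triple": {
      "type": "object",
      "required": ["base"],
      "properties": {
        "base": {"type": "number", "minimum": 0, "maximum": 1},
        "low":  {"type": "number", "minimum": 0, "maximum": 1},
        "high": {"type": "number", "minimum": 0, "maximum": 1}
      },
      "additionalProperties": false
    },
    "or_triple": {
      "type": "object",
      "required": ["base"],
      "properties": {
        "base": {"type": "number", "minimum": 0},
        "low":  {"type": "number", "minimum": 0},
        "high": {"type": "number", "minimum": 0}
      },
      "additionalProperties": false
    },
    "arm": {
      "type": "object",
      "required": ["p_nonfatal_mi", "p_nonfatal_stroke", "p_nonfatal_ua", "p_death"],
      "properties": {
        "p_nonfatal_mi":     {"$ref": "#/$defs/triple"},
        "p_nonfatal_stroke": {"$ref": "#/$defs/triple"},
        "p_nonfatal_ua":     {"$ref": "#/$defs/triple"},
        "p_death":           {"$ref": "#/$defs/triple"}
      },
      "additionalProperties": false
    },
    "post_state": {
      "type": "object",
      "required": ["p_death_y1", "p_death_later", "p_mi_y1", "p_mi_later",
                   "p_stroke_y1", "p_stroke_later"],
      "properties": {
        "p_death_y1":     {"$ref": "#/$defs/triple"},
        "p_death_later":  {"$ref": "#/$defs/triple"},
        "p_mi_y1":        {"$ref": "#/$defs/triple"},
        "p_mi_later":     {"$ref": "#/$defs/triple"},
        "p_stroke_y1":    {"$ref": "#/$defs/triple"},
        "p_stroke_later": {"$ref": "#/$defs/triple"}
      },
      "additionalProperties": false
    }
  },
  "properties": {
    "chm_arm":  {"$ref": "#/$defs/arm"},
    "conv_arm": {"$ref": "#/$defs/arm"},
    "long_term": {
      "type": "object",
      "required": ["event_free", "post_mi", "post_ua", "post_stroke",
                   "age_mace_or_per_10y"],
      "properties": {
        "event_free": {
          "type": "object",
          "required": ["p_mi", "p_stroke", "p_ua", "p_death"],
          "properties": {
            "p_mi":     {"$ref": "#/$defs/triple"},
            "p_stroke": {"$ref": "#/$defs/triple"},
            "p_ua":     {"$ref": "#/$defs/triple"},
            "p_death":  {"$ref": "#/$defs/triple"}
          },
          "additionalProperties": false
        },
        "post_mi":     {"$ref": "#/$defs/post_state"},
        "post_ua":     {"$ref": "#/$defs/post_state"},
        "post_stroke": {"$ref": "#/$defs/post_state"},
        "age_mace_or_per_10y": {"$ref": "#/$defs/or_triple"}
      },
      "additionalProperties": false
    },
    "utilities": {
      "type": "object",
      "required": ["u_event_free_chm", "u_event_free_conv",
                   "d_mi", "d_stroke", "d_ua", "d_death"],
      "properties": {
        "u_event_free_chm":  {"$ref": "#/$defs/triple"},
        "u_event_free_conv": {"$ref": "#/$defs/triple"},
        "d_mi":     {"$ref": "#/$defs/triple"},
        "d_stroke": {"$ref": "#/$defs/triple"},
        "d_ua":     {"$ref": "#/$defs/triple"},
        "d_death":  {"$ref": "#/$defs/triple"}
      },
      "additionalProperties": false
    },
    "settings": {
      "type": "object",
      "properties": {
        "horizon_years":      {"type": "integer", "minimum": 1},
        "cycle_length_years": {"const": 1},
        "discount_rate":      {"type": "number", "minimum": 0},
        "half_cycle":         {"enum": ["standard", "entry-half", "none"]},
        "disutility_mode":    {"enum": ["persistent", "one-off"]},
        "apply_age_or":       {"type": "boolean"},
        "cohort_size":        {"type": "integer", "minimum": 1}
      },
      "additionalProperties": false
    }
  },
  "additionalProperties": false
}
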