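{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "crcscreen configuration override",
  "description": "Partial override merged onto crc_basecase(); all rates are fractions in [0,1], costs are US dollars, ages and intervals whole years.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "tests": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fit_sensitivity": {"type": "number", "minimum": 0, "maximum": 1},
        "fit_specificity": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "compliance": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fit": {"type": "number", "minimum": 0, "maximum": 1},
        "colonoscopy_primary": {"type": "number", "minimum": 0, "maximum": 1},
        "colonoscopy_after_positive": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "complications": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "polypectomy_rate": {"type": "number", "minimum": 0, "maximum": 1},
        "bleeding_rate": {"type": "number", "minimum": 0, "maximum": 1},
        "perforation_rate": {"type": "number", "minimum": 0, "maximum": 1},
        "perforation_mortality": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "efficacy": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fit": {"type": "number", "minimum": 0, "maximum": 1},
        "colonoscopy": {"type": "number", "minimum": 0, "maximum": 1},
        "ai_colonoscopy": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "incidence": {
      "type": "object",
      "description": "Parallel arrays of half-open quinquennial bands, rates per 100,000 per year.",
      "additionalProperties": false,
      "properties": {
        "age_start": {"type": "array", "items": {"type": "integer"}},
        "age_end": {"type": "array", "items": {"type": "integer"}},
        "rate": {"type": "array", "items": {"type": "number", "minimum": 0}}
      }
    },
    "stages": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "distribution": {
          "type": "array", "minItems": 4, "maxItems": 4,
          "items": {"type": "number", "minimum": 0},
          "description": "Stage 1-4 shares at diagnosis; renormalized to sum to 1."
        },
        "annual_mortality": {
          "type": "array", "minItems": 4, "maxItems": 4,
          "items": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "costs": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fit_kit": {"type": "number", "minimum": 0},
        "colonoscopy": {"type": "number", "minimum": 0},
        "consultation": {"type": "number", "minimum": 0},
        "bleeding_episode": {"type": "number", "minimum": 0},
        "histopathology": {"type": "number", "minimum": 0},
        "perforation_episode": {"type": "number", "minimum": 0},
        "care_stage1": {"type": "number", "minimum": 0},
        "care_stage2": {"type": "number", "minimum": 0},
        "care_stage3": {"type": "number", "minimum": 0},
        "care_stage4": {"type": "number", "minimum": 0}
      }
    },
    "economics": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "discount_rate": {"type": "number", "minimum": 0},
        "cohort_size": {"type": "number", "exclusiveMinimum": 0},
        "start_age": {"type": "integer"},
        "screening_stop_age": {"type": "integer"},
        "horizon_age": {"type": "integer"}
      }
    },
    "schedule": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "fit_interval": {"type": "integer", "minimum": 1},
        "post_normal_hiatus": {"type": "integer", "minimum": 1},
        "surveillance_interval": {"type": "integer", "minimum": 1}
      }
    },
    "options": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "perforation_mortality_basis": {"enum": ["per_perforation", "per_colonoscopy", "per_polypectomy"]},
        "consultation_per_colonoscopy": {"type": "boolean"},
        "histopathology_per_therapeutic": {"type": "boolean"},
        "cure_years": {"type": "integer", "minimum": 1},
        "colonoscopy_protection_persists": {"type": "boolean"},
        "discount_lyl_from": {"enum": ["model_start", "death_year"]},
        "fit_reoffer": {"enum": ["annual"]}
      }
    },
    "life_table_source": {"type": "string"}
  }
}
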