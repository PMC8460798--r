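{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "emergephen pipeline report",
  "type": "object",
  "required": ["header", "sites", "rapid_change", "edaphic"],
  "properties": {
    "header": {
      "type": "object",
      "required": ["seed", "season_year", "anchor_date", "base_temp",
                   "direction", "source"],
      "properties": {
        "seed": {"type": "integer"},
        "season_year": {"type": "integer"},
        "anchor_date": {"type": "string", "format": "date"},
        "base_temp": {"type": "number"},
        "direction": {"enum": ["below_base", "above_base"]},
        "source": {"enum": ["files", "simulation"]}
      }
    },
    "sites": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["site_id", "yearly_total", "fits", "peak_window"],
        "properties": {
          "site_id": {"type": "string"},
          "yearly_total": {"type": "integer", "minimum": 1},
          "fits": {
            "type": "object",
            "additionalProperties": {
              "type": "object",
              "required": ["kind", "params", "metrics", "n_points", "converged"],
              "properties": {
                "params": {
                  "type": "object",
                  "required": ["a", "b", "c"]
                },
                "metrics": {
                  "type": "object",
                  "required": ["r2", "mae", "msle"]
                }
              }
            }
          },
          "benchmarks": {
            "type": "object",
            "additionalProperties": {
              "type": "object",
              "required": ["cdd"],
              "properties": {"cdd": {"type": "number", "minimum": 0}}
            }
          },
          "peak_window": {
            "type": "object",
            "required": ["start", "end", "length_weeks", "share"],
            "properties": {
              "share": {"type": "number", "minimum": 0, "maximum": 1}
            }
          }
        }
      }
    },
    "rapid_change": {
      "type": "object",
      "required": ["week_range", "per_week"]
    },
    "edaphic": {
      "type": "object",
      "required": ["window_days", "n_site_years", "mean", "spread"]
    },
    "screen": {"type": ["array", "null"]}
  }
}
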