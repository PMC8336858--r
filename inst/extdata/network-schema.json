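{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "mcaBounds-network-schema-v1",
  "title": "mcaBounds metabolic network",
  "type": "object",
  "required": ["metabolites", "reactions"],
  "properties": {
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "internal": {"type": "boolean", "default": true},
          "moiety_group": {"type": "string"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "stoichiometry", "net_flux"],
        "properties": {
          "id": {"type": "string"},
          "stoichiometry": {
            "type": "object",
            "description": "metabolite id -> signed coefficient; negative = substrate",
            "additionalProperties": {"type": "number"}
          },
          "net_flux": {"type": "number"},
          "rho": {
            "type": "number", "minimum": 0, "exclusiveMaximum": 1,
            "description": "disequilibrium ratio vr/vf in the oriented direction"
          },
          "boundary": {"type": "boolean", "default": false},
          "modifiers": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["metabolite", "role"],
              "properties": {
                "metabolite": {"type": "string"},
                "role": {"enum": ["activator", "inhibitor"]}
              }
            }
          },
          "competitive_pairs": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["substrate", "product"],
              "properties": {
                "substrate": {"type": "string"},
                "product": {"type": "string"}
              }
            }
          },
          "elasticity_upper": {
            "type": "object",
            "description": "metabolite id -> saturation bound h (Hill coefficient)",
            "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
          }
        }
      }
    },
    "moieties": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "members"],
        "properties": {
          "id": {"type": "string"},
          "members": {"type": "array", "items": {"type": "string"}, "minItems": 2},
          "concentration_ratios": {
            "type": "object",
            "description": "\"A/B\" -> positive ratio of member concentrations",
            "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
          }
        }
      }
    },
    "couplings": {
      "type": "array",
      "description": "groups of reaction ids with equal log-fold activity change",
      "items": {"type": "array", "items": {"type": "string"}, "minItems": 2}
    }
  }
}
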