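{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "vitacap vitamin-pathway knowledge base",
  "type": "object",
  "required": ["version", "roles", "variants"],
  "properties": {
    "version": { "type": "string" },
    "roles": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["role_id", "vitamin", "ko_ids"],
        "properties": {
          "role_id": { "type": "string", "minLength": 1 },
          "vitamin": { "enum": ["THI", "RIB", "NIA", "PAN", "PYR", "BIO", "FOL", "COB", "MEN"] },
          "ko_ids": {
            "type": "array",
            "minItems": 1,
            "items": { "type": "string", "pattern": "^K[0-9]{5}$" }
          },
          "label": { "type": "string" }
        }
      }
    },
    "variants": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["variant_id", "vitamin", "role_ids", "indispensable_role_ids"],
        "properties": {
          "variant_id": { "type": "string", "minLength": 1 },
          "vitamin": { "enum": ["THI", "RIB", "NIA", "PAN", "PYR", "BIO", "FOL", "COB", "MEN"] },
          "role_ids": { "type": "array", "minItems": 1, "items": { "type": "string" } },
          "indispensable_role_ids": { "type": "array", "minItems": 1, "items": { "type": "string" } },
          "segment_tag": { "type": "string" }
        }
      }
    },
    "cobalamin_utilization": {
      "type": "object",
      "required": ["transporters", "dependent_enzymes"],
      "properties": {
        "transporters": {
          "type": "object",
          "minProperties": 1,
          "additionalProperties": {
            "type": "array", "minItems": 1,
            "items": { "type": "string", "pattern": "^K[0-9]{5}$" }
          }
        },
        "dependent_enzymes": {
          "type": "object",
          "minProperties": 1,
          "additionalProperties": {
            "type": "array", "minItems": 1,
            "items": { "type": "string", "pattern": "^K[0-9]{5}$" }
          }
        }
      }
    }
  }
}
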