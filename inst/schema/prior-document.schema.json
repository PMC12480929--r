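{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/priorelicit/prior-document.schema.json",
  "title": "Prior document",
  "description": "A named collection of weighted Gaussian prior sets for the coefficients of one regression problem.",
  "type": "object",
  "required": ["problem_name", "sets"],
  "properties": {
    "problem_name": {"type": "string", "minLength": 1},
    "provenance": {"type": "string"},
    "sets": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["label", "informativeness", "confidence_weight", "entries"],
        "properties": {
          "label": {"type": "string", "minLength": 1},
          "informativeness": {"enum": ["weak", "moderate", "custom"]},
          "confidence_weight": {"type": "number", "minimum": 0, "maximum": 1},
          "entries": {
            "type": "object",
            "minProperties": 1,
            "additionalProperties": {
              "type": "object",
              "required": ["mean", "sd"],
              "properties": {
                "mean": {"type": "number"},
                "sd": {"type": "number", "exclusiveMinimum": 0},
                "justification": {"type": "string"},
                "sources": {"type": "array", "items": {"type": "string"}}
              }
            }
          }
        }
      }
    }
  }
}
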