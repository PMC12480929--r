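SYNTHETIC REPLAY FIXTURE (stand-in for a recorded elicitation transcript).
The confidence weights (0.65 / 0.35) reproduce reported elicitation outcomes
for this problem; every hyperparameter value is fixture-invented on a
plausible scale (MPa per kg/m^3, MPa per day of curing), not ground truth.

Reasoning (abridged, "knowledge of concrete technology"): compressive
strength rises with cement (and, more weakly, with supplementary cementitious
materials) and falls with added water; superplasticizer improves strength per
unit by enabling lower water content; aggregates act mainly as filler with
small per-unit effects; curing age raises strength, though the true
relationship is strongly non-linear, so the age prior is kept wide.

```json
{
  "problem_name": "concrete-compressive-strength",
  "provenance": "gemini-2.5-pro (synthetic replay fixture)",
  "sets": [
    {
      "label": "Gemini_Mod",
      "informativeness": "moderate",
      "confidence_weight": 0.65,
      "entries": {
        "Age": {"mean": 0.05, "sd": 0.05, "justification": "fixture-invented: kept wide, non-linear curing", "sources": ["concrete technology (fixture)"]},
        "Cement": {"mean": 0.10, "sd": 0.03, "justification": "fixture-invented", "sources": []},
        "Blast Furnace Slag": {"mean": 0.08, "sd": 0.03, "justification": "fixture-invented", "sources": []},
        "Fly Ash": {"mean": 0.07, "sd": 0.03, "justification": "fixture-invented", "sources": []},
        "Water": {"mean": -0.15, "sd": 0.06, "justification": "fixture-invented: more water weakens concrete", "sources": []},
        "Superplasticizer": {"mean": 0.25, "sd": 0.15, "justification": "fixture-invented", "sources": []},
        "Coarse Aggregate": {"mean": 0.01, "sd": 0.02, "justification": "fixture-invented", "sources": []},
        "Fine Aggregate": {"mean": 0.01, "sd": 0.02, "justification": "fixture-invented", "sources": []}
      }
    },
    {
      "label": "Gemini_Weak",
      "informativeness": "weak",
      "confidence_weight": 0.35,
      "entries": {
        "Age": {"mean": 0.0, "sd": 0.2, "justification": "fixture-invented", "sources": []},
        "Cement": {"mean": 0.0, "sd": 0.1, "justification": "fixture-invented", "sources": []},
        "Blast Furnace Slag": {"mean": 0.0, "sd": 0.1, "justification": "fixture-invented", "sources": []},
        "Fly Ash": {"mean": 0.0, "sd": 0.1, "justification": "fixture-invented", "sources": []},
        "Water": {"mean": 0.0, "sd": 0.2, "justification": "fixture-invented", "sources": []},
        "Superplasticizer": {"mean": 0.0, "sd": 0.5, "justification": "fixture-invented", "sources": []},
        "Coarse Aggregate": {"mean": 0.0, "sd": 0.05, "justification": "fixture-invented", "sources": []},
        "Fine Aggregate": {"mean": 0.0, "sd": 0.05, "justification": "fixture-invented", "sources": []}
      }
    }
  ]
}
```
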