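SYNTHETIC REPLAY FIXTURE (stand-in for a recorded elicitation transcript).
The confidence weights (0.60 / 0.40) and the sex prior N(0.7, 0.3) reproduce
reported elicitation outcomes for this problem; every other hyperparameter is
a fixture-invented plausible value, not ground truth.

Reasoning (abridged): literature reports odds ratios for male sex in the
range 1.8-2.5, i.e. log odds ratios 0.6-0.9; the mean 0.7 with sd 0.3 covers
that interval with a safe margin. The weakly informative set centres every
coefficient at zero with wide spreads, expressing direction-agnostic caution.

```json
{
  "problem_name": "heart-disease",
  "provenance": "chatgpt-4o-mini (synthetic replay fixture)",
  "sets": [
    {
      "label": "ChatGPT_Mod",
      "informativeness": "moderate",
      "confidence_weight": 0.60,
      "entries": {
        "age": {"mean": 0.08, "sd": 0.015, "justification": "fixture-invented", "sources": ["Framingham Heart Study", "MESA study"]},
        "sex": {"mean": 0.7, "sd": 0.3, "justification": "odds ratios 1.8-2.5 -> log odds 0.6-0.9; centred at 0.7", "sources": ["Framingham Heart Study", "meta-analyses"]},
        "trestbps": {"mean": 0.01, "sd": 0.008, "justification": "fixture-invented", "sources": []},
        "chol": {"mean": 0.004, "sd": 0.002, "justification": "fixture-invented", "sources": []},
        "thalach": {"mean": -0.02, "sd": 0.008, "justification": "fixture-invented", "sources": []},
        "oldpeak": {"mean": 0.45, "sd": 0.15, "justification": "fixture-invented", "sources": []}
      }
    },
    {
      "label": "ChatGPT_Weak",
      "informativeness": "weak",
      "confidence_weight": 0.40,
      "entries": {
        "age": {"mean": 0.0, "sd": 1.0, "justification": "fixture-invented: zero-centred, very wide", "sources": []},
        "sex": {"mean": 0.0, "sd": 2.5, "justification": "fixture-invented", "sources": []},
        "trestbps": {"mean": 0.0, "sd": 1.0, "justification": "fixture-invented", "sources": []},
        "chol": {"mean": 0.0, "sd": 1.0, "justification": "fixture-invented", "sources": []},
        "thalach": {"mean": 0.0, "sd": 1.0, "justification": "fixture-invented", "sources": []},
        "oldpeak": {"mean": 0.0, "sd": 2.0, "justification": "fixture-invented", "sources": []}
      }
    }
  ]
}
```
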