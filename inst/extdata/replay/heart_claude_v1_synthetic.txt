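SYNTHETIC REPLAY FIXTURE (stand-in for a recorded elicitation transcript).
The confidence weights (0.65 / 0.35) and the sex prior N(0.7, 0.3) reproduce
reported elicitation outcomes for this problem; every other hyperparameter is
a fixture-invented plausible value, not ground truth.

Reasoning (abridged): coronary artery disease risk roughly doubles for males
relative to females in large cohort studies (Framingham, MONICA), giving a
log odds ratio of ln 2 ~ 0.7 with moderate uncertainty 0.3. Age, resting
blood pressure, cholesterol and exercise-induced ST depression carry positive
per-unit associations on the log-odds scale; maximum heart rate achieved is
protective. Verification pass: signs checked against the epidemiological
consensus, magnitudes converted to per-unit log-odds.

```json
{
  "problem_name": "heart-disease",
  "provenance": "claude-opus (synthetic replay fixture)",
  "sets": [
    {
      "label": "Claude_Mod",
      "informativeness": "moderate",
      "confidence_weight": 0.65,
      "entries": {
        "age": {"mean": 0.06, "sd": 0.02, "justification": "fixture-invented: ~6% odds increase per year", "sources": ["cohort studies (fixture)"]},
        "sex": {"mean": 0.7, "sd": 0.3, "justification": "males ~twice the odds; ln 2 ~ 0.7, moderate uncertainty", "sources": ["Framingham Heart Study", "MONICA project"]},
        "trestbps": {"mean": 0.02, "sd": 0.01, "justification": "fixture-invented: per mmHg", "sources": ["meta-analyses (fixture)"]},
        "chol": {"mean": 0.005, "sd": 0.003, "justification": "fixture-invented: per mg/dl", "sources": ["meta-analyses (fixture)"]},
        "thalach": {"mean": -0.03, "sd": 0.012, "justification": "fixture-invented: higher achievable heart rate is protective", "sources": ["exercise physiology (fixture)"]},
        "oldpeak": {"mean": 0.5, "sd": 0.2, "justification": "fixture-invented: per mm ST depression", "sources": ["stress-test literature (fixture)"]}
      }
    },
    {
      "label": "Claude_Weak",
      "informativeness": "weak",
      "confidence_weight": 0.35,
      "entries": {
        "age": {"mean": 0.05, "sd": 0.06, "justification": "fixture-invented: same direction, tripled width", "sources": []},
        "sex": {"mean": 0.6, "sd": 0.8, "justification": "fixture-invented: non-zero centre kept, widened", "sources": []},
        "trestbps": {"mean": 0.015, "sd": 0.03, "justification": "fixture-invented", "sources": []},
        "chol": {"mean": 0.004, "sd": 0.009, "justification": "fixture-invented", "sources": []},
        "thalach": {"mean": -0.02, "sd": 0.04, "justification": "fixture-invented", "sources": []},
        "oldpeak": {"mean": 0.4, "sd": 0.6, "justification": "fixture-invented", "sources": []}
      }
    }
  ]
}
```
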