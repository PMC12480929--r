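Variable	Claude_Weak	Gemini_Weak	Claude_Mod	ChatGPT_Mod	Gemini_Mod	ChatGPT_Weak
Age	0.60	1.21	2.77	1.72	3.32	4.40
Sex	2.21	2.05	5.61	5.61	18.00	1.70
Trestbps	0.44	1.29	0.13	3.98	1.04	5.14
Chol	0.79	1.49	0.24	0.78	0.27	6.25
Thalach	1.44	1.63	3.83	1.58	1.58	5.24
Oldpeak	0.92	1.64	0.30	0.64	0.05	2.38
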