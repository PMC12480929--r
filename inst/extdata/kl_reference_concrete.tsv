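Variable	Gemini_Mod	Claude_Mod	Gemini_Weak	Claude_Weak	ChatGPT_Weak	ChatGPT_Mod
Cement	1.37	1.37	2.84	2.72	4.28	10.53
Blast furnace slag	1.51	1.08	2.62	2.55	4.10	9.10
Fly ash	1.16	1.16	2.36	2.33	3.88	13.52
Water	0.22	1.62	1.41	1.53	2.73	0.54
Superplasticizer	0.21	3.33	1.37	3.00	1.92	0.95
Coarse aggregate	0.37	0.37	1.89	1.87	4.17	41.33
Fine aggregate	0.27	0.27	1.76	1.75	4.04	68.27
Age	3.59	4.14	4.72	4.04	4.72	35.73
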