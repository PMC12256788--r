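sample_id	assembled_fraction	mean_depth	assay	tissue
S01	0.95	80	ES	blood
S02	0.40	60	ES	blood
S03	0.80	35	ES	blood
S04	0.62	12	ES	blood
S05	0.90	100	GS	blood
S06	0.75	50	ES	blood
S07	1.00	4.5	ES	blood
S08	0.50	5	ES	muscle
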