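subject_id	label	hpo_terms
REF001	MELAS-like syndrome	SP:0000105;SP:0000101;SP:0000501;SP:0000104;SP:0000110;SP:0000202;SP:0000502;SP:0000402
REF002	MERRF-like syndrome	SP:0000113;SP:0000101;SP:0000107;SP:0000202;SP:0000501
REF003	LHON-like optic neuropathy	SP:0000301;SP:0000303
REF004	Leigh-like syndrome	SP:0000108;SP:0000115;SP:0000501;SP:0000209;SP:0000114;SP:0000106
REF005	CPEO-like myopathy	SP:0000208;SP:0000206;SP:0000204;SP:0000203
REF006	KSS-like multisystem disease	SP:0000208;SP:0000304;SP:0000605;SP:0000801;SP:0000107
REF007	MIDD-like diabetes-deafness	SP:0000502;SP:0000402
REF008	NARP-like syndrome	SP:0000111;SP:0000106;SP:0000304
REF009	Nonsyndromic sensorineural deafness	SP:0000402
REF010	Pearson-like marrow-pancreas syndrome	SP:0000704;SP:0000802;SP:0000901;SP:0000504
REF011	MNGIE-like gastrointestinal encephalomyopathy	SP:0000702;SP:0000703;SP:0000111;SP:0000204;SP:0000802
REF012	Mitochondrial encephalomyopathy	SP:0000104;SP:0000202;SP:0000501;SP:0000101;SP:0000109
REF013	Exercise-induced myopathy with rhabdomyolysis	SP:0000210;SP:0000203;SP:0000204;SP:0000501
REF014	Optic atrophy plus syndrome	SP:0000301;SP:0000106;SP:0000111;SP:0000402
REF015	Mitochondrial cardiomyopathy	SP:0000602;SP:0000204;SP:0000501;SP:0000803
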