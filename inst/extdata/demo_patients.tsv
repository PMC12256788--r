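sample_id	hpo_terms
S01	SP:0000105;SP:0000101;SP:0000501;SP:0000202;SP:0000402
S02	SP:0000109;SP:0000101
S03	SP:0000111;SP:0000106;SP:0000304;SP:0000803
S04	SP:0000204;SP:0000203;SP:0000501
S05	SP:0000305
S06	SP:0000109;SP:0000802
S07	SP:0000402
S08	SP:0000402;SP:0000401
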