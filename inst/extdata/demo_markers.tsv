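haplogroup	position	ref	alt
H	7028	C	T
H	2706	A	G
H	1438	A	G
J	295	C	T
J	489	T	C
J	10398	A	G
J	12612	G	A
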