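sample_id	position	ref	alt	heteroplasmy	depth
S01	7028	C	T	0.99	80
S01	2706	A	G	0.99	80
S01	3243	A	G	0.33	80
S01	16189	T	C	0.60	80
S02	8344	A	G	0.80	60
S03	295	C	T	0.99	35
S03	489	T	C	0.99	35
S03	10398	A	G	0.97	35
S03	9176	T	C	0.95	35
S04	5698	G	A	0.50	12
S04	9032	T	C	0.60	12
S04	15990	C	T	0.40	12
S05	3243	A	G	0.005	100
S05	14696	A	G	1.00	100
S06	7028	C	T	0.98	50
S06	2706	A	G	0.99	50
S06	11914	G	A	0.70	50
S07	1555	A	G	0.99	4.5
S08	295	C	T	0.99	5
S08	1555	A	G	0.62	5
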