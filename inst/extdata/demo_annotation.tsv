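position	ref	alt	mitomap_status	mitomap_af	in_mitophen	gene	actionable
3243	A	G	confirmed	0.0001	TRUE	MT-TL1	FALSE
8344	A	G	confirmed	0.0001	TRUE	MT-TK	FALSE
9176	T	C	reported	0.0002	TRUE	MT-ATP6	FALSE
5698	G	A	reported	0.0005	FALSE	MT-TN	FALSE
9032	T	C	reported	0.003	FALSE	MT-ATP6	FALSE
1555	A	G	confirmed	0.001	TRUE	MT-RNR1	TRUE
14696	A	G	reported	0.01	FALSE	MT-ND6	FALSE
16189	T	C	reported	0.05	FALSE	MT-DLOOP	FALSE
15990	C	T	reported	NA	FALSE	MT-TP	FALSE
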