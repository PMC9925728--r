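subfamily	position	residue	freq
AhpC-PRX1	1	P	1
AhpC-PRX1	2	L	0.7
AhpC-PRX1	2	V	0.3
AhpC-PRX1	3	D	1
AhpC-PRX1	4	F	0.7
AhpC-PRX1	4	Y	0.3
AhpC-PRX1	5	T	1
AhpC-PRX1	6	F	1
AhpC-PRX1	7	V	1
AhpC-PRX1	8	C	1
AhpC-PRX1	9	P	1
AhpC-PRX1	10	T	1
AhpC-PRX1	11	E	0.7
AhpC-PRX1	11	D	0.3
AhpC-PRX1	12	I	1
AhpC-PRX1	13	I	1
AhpC-PRX1	14	A	1
AhpC-PRX1	15	F	1
PRX5	1	P	1
PRX5	2	G	0.7
PRX5	2	A	0.3
PRX5	3	A	0.7
PRX5	3	S	0.3
PRX5	4	F	1
PRX5	5	T	1
PRX5	6	P	0.7
PRX5	6	A	0.3
PRX5	7	G	1
PRX5	8	C	1
PRX5	9	S	1
PRX5	10	K	0.7
PRX5	10	R	0.3
PRX5	11	T	1
PRX5	12	H	0.7
PRX5	12	N	0.3
PRX5	13	L	1
PRX5	14	P	1
PRX5	15	G	1
PRX6	1	P	1
PRX6	2	G	1
PRX6	3	D	0.7
PRX6	3	E	0.3
PRX6	4	F	1
PRX6	5	T	1
PRX6	6	P	1
PRX6	7	V	1
PRX6	8	C	1
PRX6	9	T	1
PRX6	10	T	1
PRX6	11	E	1
PRX6	12	L	0.7
PRX6	12	M	0.3
PRX6	13	G	1
PRX6	14	R	1
PRX6	15	A	1
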