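position	residue	weight
6	A	0
6	C	0
6	D	0
6	E	0
6	F	0
6	G	0
6	H	0
6	I	0
6	K	0
6	L	0
6	M	0
6	N	0
6	P	0
6	Q	0
6	R	0
6	S	0
6	T	0
6	V	0
6	W	0
6	Y	1
7	A	0
7	C	0
7	D	0
7	E	0
7	F	0
7	G	0
7	H	0
7	I	0
7	K	0
7	L	0
7	M	0
7	N	0
7	P	0
7	Q	0
7	R	0
7	S	0
7	T	0
7	V	0
7	W	1
7	Y	0
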