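position	residue	weight
6	A	
6	C	
6	D	
6	E	
6	F	
6	G	
6	H	
6	I	
6	K	
6	L	
6	M	
6	N	
6	P	
6	Q	
6	R	
6	S	
6	T	
6	V	
6	W	
6	Y	
7	A	
7	C	
7	D	
7	E	
7	F	
7	G	
7	H	
7	I	
7	K	
7	L	
7	M	
7	N	
7	P	
7	Q	
7	R	
7	S	
7	T	
7	V	
7	W	
7	Y	
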