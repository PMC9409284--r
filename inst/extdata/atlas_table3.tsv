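table	group	raw	wt	native	universal	sub	site	region	species	figures	note
table3	1	D59G	D	59		G	linker_other	N-terminus	Blattella germanica
table3	2	A99S	A	99		S	linker_other	N-terminus	Culex quinquefasciatus
table3	3	I254/1k12N	I	254	1k12	N	beyond	IS4-S5	Drosophila melanogaster
table3	4	E435/1i45K	E	435	1i45	K	beyond	IS6	Blattella germanica
table3	5	C785R	C	785		R	linker_other	I-II	Blattella germanica
table3	6	M827/IIS1-S2I	M	827		I	beyond	IIS1-S2	P. humanus capitis	5a	impact PyR1
table3	7	G943/2o24A	G	943	2o24	A	beyond	IIS5	P. humanus capitis	5b	impact PyR1, PyR2
table3	8	Q945/2o26R	Q	945	2o26	R	beyond	IIS5	L. salmonis	5b	impact PyR2
table3	9	S989/2p55P	S	989	2p55	P	beyond	IIP1-P2	Aedes aegypti	5c,2a,c	impact IIP1-P2
table3	9	V1016/2i18G	V	1016	2i18	G	PyR1		Aedes aegypti	5c,2a,c	impact PyR1
table3	10	A1101T	A	1101		T	linker_other	II-III	Plutella xylostella
table3	10	P1879/CTDS	P	1879		S	linker_other	CTD	Plutella xylostella
table3	11	A1410/3k10V	A	1410	3k10	V	beyond	IIIS4-S5	Drosophila melanogaster	6a	impact PyR1
table3	12	A1494/3p47V	A	1494	3p47	V	beyond	IIIP2	Drosophila melanogaster	6b	impact PyR1
table3	13	M1524/3i3I	M	1524	3i3	I	beyond	IIIS6	Drosophila melanogaster	6c	impact PyR1
table3	14	F1528/3i7L	F	1528	3i7	L	beyond	IIIS6	Varroa destructor	6d	impact PyR1
table3	14	M1823/4i3I	M	1823	4i3	I	beyond	IVS6	Varroa destructor	6d	impact IVS6
table3	15	D1549/3i28V	D	1549	3i28	V	beyond	IIIS6	Helicoverpa armigera	6e	impact PyR1, PyR2
table3	15	E1553/3i32G	E	1553	3i32	G	beyond	IIIS6	Helicoverpa armigera	6e	impact PyR1, PyR2
table3	16	A1215D	A	1215		D	linker_other	II-III	Tetranychus urticae
table3	16	F1538/3i17I	F	1538	3i17	I	PyR1		Tetranychus urticae		impact PyR1
table3	17	W1594R	W	1594		R	linker_other	IVS0-N	Culex quinquefasciatus
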