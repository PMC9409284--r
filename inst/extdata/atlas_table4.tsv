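table	group	raw	wt	native	universal	sub	site	region	species	figures	note
table4	1	I249/1k7A	I	249	1k7	A	beyond	IS4-S5	Aedes aegypti	5d	impact PyR2, PyR1
table4	2	S420/1i29A	S	420	1i29	A	beyond	IS6	Aedes aegypti	5e	impact PyR1
table4	3	D823G/A/K	D	823		G/A/K	beyond	IIS1-S2	Blattella germanica	5a	impact PyR1
table4	4	L914/2k7F/I	L	914	2k7	F/I	beyond	IIS4-S5	Drosophila melanogaster	6f	impact PyR1
table4	5	N927/2o8I	N	927	2o8	I	beyond	IIS5	Drosophila melanogaster	5f	impact PyR1, PyR2
table4	6	A1410/3k10V	A	1410	3k10	V	beyond	IIIS4-S5	Blattella germanica	6a	impact PyR1
table4	7	A1494/3p47V	A	1494	3p47	V	beyond	IIIP2	Blattella germanica	6b	impact PyR1
table4	8	G1535/3i14A	G	1535	3i14	A	beyond	IIIS6	Blattella germanica		gating hinge in IIIS6
table4	9	N1541/3i20A	N	1541	3i20	A	beyond	IIIS6	Blattella germanica		impact PyR1
table4	10	D1549/3i28V	D	1549	3i28	V	beyond	IIIS6	Blattella germanica	6e
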