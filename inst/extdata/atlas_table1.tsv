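table	group	raw	wt	native	universal	sub	site	region	species	figures	note
table1	1	V253/1k11F	V	253	1k11	F	PyR2		Aedes aegypti	2b,d
table1	2	T267/1o13A	T	267	1o13	A	PyR2		Plant hopper	2b,d
table1	3	V410/1i19M	V	410	1i19	M	PyR2		Helicoverpa zea	2b,d
table1	4	V410/1i19L	V	410	1i19	L	PyR2		Cimex luctularis	2b,d
table1	5	V410/1i19G/A	V	410	1i19	G/A	PyR2		Helicoverpa zea	2b,d
table1	6	V1010/2i12L	V	1010	2i12	L	PyR2		Anopheles culicifacies	2b,d
table1	6	L1014/2i16S	L	1014	2i16	S	PyR2		Anopheles culicifacies	2b,d
table1	7	I1011/2i13M	I	1011	2i13	M	PyR2		Aedes aegypti	2b,d
table1	8	I1011/2i13V	I	1011	2i13	V	PyR2		Aedes aegypti	2b,d
table1	9	N1013/2i15S	N	1013	2i15	S	PyR2		Anopheles sinensis	2b,d
table1	10	L1014/2i16F	L	1014	2i16	F	PyR2		Anopheles gambiae	2b,d
table1	11	L1014/2i16S	L	1014	2i16	S	PyR2		Anopheles arabiensis	2b,d
table1	12	L1014/2i16H	L	1014	2i16	H	PyR2		Helicoverpa zea	2b,d
table1	13	L1014/2i16C	L	1014	2i16	C	PyR2		Anopheles sinensis	2b,d
table1	14	L1014/2i16W	L	1014	2i16	W	PyR2		Anopheles sinensis	2b,d
table1	15	L1014/2i16F	L	1014	2i16	F	PyR2		Myzus persicae	2b,d
table1	15	F979S	F	979		S	beyond	IIP1	Myzus persicae	2b,d
table1	16	L1014/2i16F	L	1014	2i16	F	PyR2		Anopheles gambiae	2b,d
table1	16	N1575Y	N	1575		Y	linker_other	III-IV	Anopheles gambiae	2b,d
table1	17	L1014/2i16F	L	1014	2i16	F	PyR2		Blattella germanica	2b,d
table1	17	E435K	E	435		K	beyond	IS6	Blattella germanica	2b,d
table1	17	C785R	C	785		R	linker_other		Blattella germanica	2b,d
table1	18	M918/2k11T	M	918	2k11	T	PyR1		Haematobia i. irritans	1c,4a,b,d
table1	18	L1014/2i16F	L	1014	2i16	F	PyR2		Haematobia i. irritans	1c,4a,b,d
table1	19	M918/2k11L	M	918	2k11	L	PyR1		Thrips tabaci	1c,2a
table1	19	V1010/2i12A	V	1010	2i12	A	PyR2		Thrips tabaci	1c,2a
table1	20	M918/2k11I	M	918	2k11	I	PyR1		Plutella xylostella	1c,2a,b,d
table1	20	L1014/2i16F	L	1014	2i16	F	PyR2		Plutella xylostella	1c,2a,b,d
table1	21	T929/2o10I	T	929	2o10	I	PyR1		Frankliniella occidentalis	1c,2a,b,d
table1	21	L1014/2i16F	L	1014	2i16	F	PyR2		Frankliniella occidentalis	1c,2a,b,d
table1	22	T929/2o10I	T	929	2o10	I	PyR1		Plutella xylostella	1c,2a,b,d
table1	22	L1014/2i16F	L	1014	2i16	F	PyR2		Plutella xylostella	1c,2a,b,d
table1	23	T929/2o10C	T	929	2o10	C	PyR1		Frankliniella occidentalis	1c,2a
table1	23	L1014/2i16F	L	1014	2i16	F	PyR2		Frankliniella occidentalis	1c,2a
table1	24	T929/2o10V	T	929	2o10	V	PyR1		Ctenocephalides felis	1c,2a
table1	24	L1014/2i16F	L	1014	2i16	F	PyR2		Ctenocephalides felis	1c,2a
table1	25	T929/2o10N	T	929	2o10	N	PyR1		L. decemlineata	1c,2a,b,d
table1	25	L1014/2i16F	L	1014	2i16	F	PyR2		L. decemlineata	1c,2a,b,d
table1	26	F979/2p44S	F	979	2p44	S	PyR1		Myzus persicae	1c,2a,b,d
table1	26	L1014/2i16F	L	1014	2i16	F	PyR2		Myzus persicae	1c,2a,b,d
table1	27	M918/2k11T	M	918	2k11	T	PyR1		Aphis gossypii	1c,2a
table1	28	M918/2k11L	M	918	2k11	L	PyR1		Aphis gossypii	1c,2a
table1	29	M918/2k11L	M	918	2k11	L	PyR1		Trialeurodes vaporariorum	1c,2a
table1	29	L925/2o6I	L	925	2o6	I	PyR1		Trialeurodes vaporariorum	1c,2a
table1	30	M918/2k11V	M	918	2k11	V	PyR1		Bemisia tabaci	1c,2a
table1	31	L925/2o6I	L	925	2o6	I	PyR1		Bemisia tabaci	1c,2a
table1	32	L925/2o6V	L	925	2o6	V	PyR1		Varroa destructor	1c,2a
table1	33	T929/2o10I	T	929	2o10	I	PyR1		Thrips tabaci	1c,2a
table1	34	T929/2o10I	T	929	2o10	I	PyR1		P. humanus capitis	1c,2a
table1	34	L932/2o13F	L	932	2o13	F	PyR1		P. humanus capitis	1c,2a
table1	35	T929/2o10I	T	929	2o10	I	PyR1		P. humanus capitis	1c,2a
table1	35	M827I	M	827		I	beyond	IIS1-S2	P. humanus capitis	1c,2a
table1	36	T929/2o10C	T	929	2o10	C	PyR1		Frankliniella occidentalis	1c,2a
table1	37	T929/2o10V	T	929	2o10	V	PyR1		Bemisia tabaci	1c,2a
table1	38	L932/2o13F	L	932	2o13	F	PyR1		P. humanus capitis	1c,2a
table1	38	M827I	M	827		I	beyond	IIS1-S2	P. humanus capitis	1c,2a
table1	39	I936/2o17V	I	936	2o17	V	PyR1		Helicoverpa zea	1c,2a
table1	40	L982/2p47W	L	982	2p47	W	PyR1		Aedes aegypti	1c
table1	41	V1016/2i18G	V	1016	2i18	G	PyR1		Aedes aegypti	2a,c
table1	42	V1016/2i18G	V	1016	2i18	G	PyR1		Aedes aegypti	2a,c
table1	42	S989/2p55P	S	989	2p55	P	beyond	IIP1-P2	Aedes aegypti	2a,c
table1	43	V1016/2i18G	V	1016	2i18	G	PyR1		Aedes aegypti	2a,c
table1	43	D1763Y	D	1763		Y	beyond	IVS5-P1	Aedes aegypti	2a,c
table1	44	V1016/2i18I	V	1016	2i18	I	PyR1		Aedes aegypti	2a,c
table1	45	F1020/2i22S	F	1020	2i22	S	PyR1		Blattella germanica	2a
table1	46	L1024/2i26V	L	1024	2i26	V	PyR1		Tetranychus urticae	1c,S5b
table1	47	F1534/3i13C	F	1534	3i13	C	PyR1		Aedes aegypti	1c,2a
table1	48	F1534/3i13L	F	1534	3i13	L	PyR1		Aedes aegypti	1c,2a
table1	49	F1537/3i16L	F	1537	3i16	L	PyR1		Dermanyssus gallinae	1c
table1	50	F1538/3i17I	F	1538	3i17	I	PyR1		Rhipicephalus microplus	1c,2a
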