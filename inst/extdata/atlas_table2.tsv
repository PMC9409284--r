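table	group	raw	wt	native	universal	sub	site	region	species	figures	note
table2	1	L260/1o6A	L	260	1o6	A	PyR2		AaNav1-1	2b,d
table2	2	I264/1o10C	I	264	1o10	C	PyR2		AaNav1-1	2b,d
table2	3	I413/1i22A	I	413	1i22	A	PyR2		AaNav1-1	2b,d
table2	4	M918/2k11T	M	918	2k11	T	PyR1		DmNav	4c,2a,c
table2	5	V922/2o3I	V	922	2o3	I	PyR1		BiNav1-1	6c	M2o3 in AaNav1-1a
table2	6	L925/2o6I	L	925	2o6	I	PyR1		DmNav	1c
table2	7	T929/2o10I	T	929	2o10	I	PyR1		DmNav	1c,2a
table2	8	L932/2o13F	L	932	2o13	F	PyR1		DmNav	1c,2a
table2	9	C933/2o14A	C	933	2o14	A	PyR1		DmNav	1c,2a
table2	10	I936/2o17V	I	936	2o17	V	PyR1		DmNav	1c,2a
table2	11	N1013/2i15S	N	1013	2i15	S	PyR2		AaNav1-1	2b,d
table2	12	F1020/2i22S	F	1020	2i22	S	PyR1		AaNav1-1	1c,2a
table2	13	L1023/2i25A	L	1023	2i25	A	PyR1		AaNav1-1	2a
table2	14	L1024/2i26A	L	1024	2i26	A	PyR1		AaNav1-1	1c
table2	15	F1526/3i5L	F	1526	3i5	L	PyR1		BiNav1-1	6c	tau-fluvalinate
table2	16	V1529/3i8A	V	1529	3i8	A	PyR1		BiNav1-1	1c,2a	tau-fluvalinate
table2	17	I1533/3i12A	I	1533	3i12	A	PyR1		BgNav1-1a	1c,2a
table2	18	F1537/3i16A	F	1537	3i16	A	PyR1		BgNav1-1a	2a
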