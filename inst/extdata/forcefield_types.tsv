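type	eps	sigma	hbd	hba	element
CT	0.12	3.40	FALSE	FALSE	C
CAr	0.12	3.30	FALSE	FALSE	C
CO	0.10	3.20	FALSE	FALSE	C
CN	0.15	3.10	FALSE	FALSE	C
OC	0.20	2.70	FALSE	TRUE	O
OS	0.17	2.75	FALSE	TRUE	O
OH	0.20	2.75	TRUE	TRUE	O
OD	0.20	2.70	FALSE	TRUE	O
SM	0.25	3.20	FALSE	TRUE	S
SH	0.25	3.20	TRUE	TRUE	S
NC	0.16	2.95	FALSE	TRUE	N
NG	0.16	2.95	TRUE	FALSE	N
BR	0.40	3.40	FALSE	FALSE	Br
CL	0.30	3.20	FALSE	FALSE	Cl
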