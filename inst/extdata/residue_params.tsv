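resid	elety	type	charge
ALA	CA	CT	0
ALA	CB	CT	0
GLY	CA	CT	0
CYS	CA	CT	0
CYS	CB	CT	0.15
CYS	SG	SH	-0.15
SER	CA	CT	0
SER	CB	CT	0.35
SER	OG	OH	-0.35
THR	CA	CT	0
THR	CB	CT	0.35
THR	OG1	OH	-0.35
MET	CA	CT	0
MET	CB	CT	0
MET	CG	CT	0.15
MET	SD	SM	-0.30
MET	CE	CT	0.15
ASP	CA	CT	0
ASP	CB	CT	0
ASP	CG	CO	0.20
ASP	OD1	OD	-0.60
ASP	OD2	OD	-0.60
ARG	CA	CT	0
ARG	CB	CT	0
ARG	CG	CT	0
ARG	CD	CT	0.10
ARG	NE	NG	0.20
ARG	CZ	CO	0.30
ARG	NH1	NG	0.20
ARG	NH2	NG	0.20
PHE	CA	CT	0
PHE	CB	CT	0
PHE	CG	CAr	0
PHE	CD1	CAr	0
PHE	CD2	CAr	0
PHE	CE1	CAr	0
PHE	CE2	CAr	0
PHE	CZ	CAr	0
LEU	CA	CT	0
LEU	CB	CT	0
LEU	CG	CT	0
LEU	CD1	CT	0
LEU	CD2	CT	0
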