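resid	elety	type	charge
ALA	N	N	0.25
ALA	CA	CT	0
ALA	C	C	0.55
ALA	O	O	-0.8
ALA	CB	CT	0
ARG	N	N	0.25
ARG	CA	CT	0
ARG	C	C	0.55
ARG	O	O	-0.8
ARG	CB	CT	0
ARG	CG	CT	0
ARG	CD	CT	0
ARG	NE	N	0
ARG	CZ	C	0.5
ARG	NH1	N	0.25
ARG	NH2	N	0.25
ASN	N	N	0.25
ASN	CA	CT	0
ASN	C	C	0.55
ASN	O	O	-0.8
ASN	CB	CT	0
ASN	CG	C	0.55
ASN	OD1	O	-0.55
ASN	ND2	N	0
ASP	N	N	0.25
ASP	CA	CT	0
ASP	C	C	0.55
ASP	O	O	-0.8
ASP	CB	CT	0
ASP	CG	C	0.3
ASP	OD1	O2	-0.65
ASP	OD2	O2	-0.65
CYS	N	N	0.25
CYS	CA	CT	0
CYS	C	C	0.55
CYS	O	O	-0.8
CYS	CB	CT	0.1
CYS	SG	S	-0.1
GLN	N	N	0.25
GLN	CA	CT	0
GLN	C	C	0.55
GLN	O	O	-0.8
GLN	CB	CT	0
GLN	CG	CT	0
GLN	CD	C	0.55
GLN	OE1	O	-0.55
GLN	NE2	N	0
GLU	N	N	0.25
GLU	CA	CT	0
GLU	C	C	0.55
GLU	O	O	-0.8
GLU	CB	CT	0
GLU	CG	CT	0
GLU	CD	C	0.3
GLU	OE1	O2	-0.65
GLU	OE2	O2	-0.65
GLY	N	N	0.25
GLY	CA	CT	0
GLY	C	C	0.55
GLY	O	O	-0.8
HIS	N	N	0.25
HIS	CA	CT	0
HIS	C	C	0.55
HIS	O	O	-0.8
HIS	CB	CT	0
HIS	CG	CR	0
HIS	ND1	N	-0.15
HIS	CD2	CR	0
HIS	CE1	CR	0.3
HIS	NE2	N	-0.15
ILE	N	N	0.25
ILE	CA	CT	0
ILE	C	C	0.55
ILE	O	O	-0.8
ILE	CB	CT	0
ILE	CG1	CT	0
ILE	CG2	CT	0
ILE	CD1	CT	0
LEU	N	N	0.25
LEU	CA	CT	0
LEU	C	C	0.55
LEU	O	O	-0.8
LEU	CB	CT	0
LEU	CG	CT	0
LEU	CD1	CT	0
LEU	CD2	CT	0
LYS	N	N	0.25
LYS	CA	CT	0
LYS	C	C	0.55
LYS	O	O	-0.8
LYS	CB	CT	0
LYS	CG	CT	0
LYS	CD	CT	0
LYS	CE	CT	0.25
LYS	NZ	N3	0.75
MET	N	N	0.25
MET	CA	CT	0
MET	C	C	0.55
MET	O	O	-0.8
MET	CB	CT	0
MET	CG	CT	0
MET	SD	S	0
MET	CE	CT	0
PHE	N	N	0.25
PHE	CA	CT	0
PHE	C	C	0.55
PHE	O	O	-0.8
PHE	CB	CT	0
PHE	CG	CR	0
PHE	CD1	CR	0
PHE	CD2	CR	0
PHE	CE1	CR	0
PHE	CE2	CR	0
PHE	CZ	CR	0
PRO	N	N	0.25
PRO	CA	CT	0
PRO	C	C	0.55
PRO	O	O	-0.8
PRO	CB	CT	0
PRO	CG	CT	0
PRO	CD	CT	0
SER	N	N	0.25
SER	CA	CT	0
SER	C	C	0.55
SER	O	O	-0.8
SER	CB	CT	0.25
SER	OG	OH	-0.25
THR	N	N	0.25
THR	CA	CT	0
THR	C	C	0.55
THR	O	O	-0.8
THR	CB	CT	0.25
THR	OG1	OH	-0.25
THR	CG2	CT	0
TRP	N	N	0.25
TRP	CA	CT	0
TRP	C	C	0.55
TRP	O	O	-0.8
TRP	CB	CT	0
TRP	CG	CR	0
TRP	CD1	CR	0.15
TRP	CD2	CR	0
TRP	NE1	N	-0.15
TRP	CE2	CR	0
TRP	CE3	CR	0
TRP	CZ2	CR	0
TRP	CZ3	CR	0
TRP	CH2	CR	0
TYR	N	N	0.25
TYR	CA	CT	0
TYR	C	C	0.55
TYR	O	O	-0.8
TYR	CB	CT	0
TYR	CG	CR	0
TYR	CD1	CR	0
TYR	CD2	CR	0
TYR	CE1	CR	0
TYR	CE2	CR	0
TYR	CZ	CR	0.25
TYR	OH	OH	-0.25
VAL	N	N	0.25
VAL	CA	CT	0
VAL	C	C	0.55
VAL	O	O	-0.8
VAL	CB	CT	0
VAL	CG1	CT	0
VAL	CG2	CT	0
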