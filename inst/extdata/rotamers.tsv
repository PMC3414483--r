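resid	chi1	chi2	chi3	chi4	prob
SER	64	NA	NA	NA	0.48
SER	-66	NA	NA	NA	0.29
SER	178	NA	NA	NA	0.23
CYS	-65	NA	NA	NA	0.55
CYS	-177	NA	NA	NA	0.26
CYS	63	NA	NA	NA	0.19
THR	62	NA	NA	NA	0.49
THR	-59	NA	NA	NA	0.43
THR	-175	NA	NA	NA	0.08
VAL	175	NA	NA	NA	0.73
VAL	-64	NA	NA	NA	0.20
VAL	64	NA	NA	NA	0.07
LEU	-65	175	NA	NA	0.59
LEU	-177	65	NA	NA	0.28
LEU	-85	65	NA	NA	0.13
ILE	-65	170	NA	NA	0.60
ILE	-57	-60	NA	NA	0.15
ILE	62	170	NA	NA	0.13
ILE	-65	100	NA	NA	0.12
MET	-65	-65	-70	NA	0.30
MET	-65	180	75	NA	0.25
MET	180	180	180	NA	0.25
MET	-65	180	180	NA	0.20
PHE	-65	90	NA	NA	0.55
PHE	180	80	NA	NA	0.30
PHE	62	90	NA	NA	0.15
TYR	-65	90	NA	NA	0.55
TYR	180	80	NA	NA	0.30
TYR	62	90	NA	NA	0.15
TRP	-65	95	NA	NA	0.40
TRP	180	-105	NA	NA	0.35
TRP	62	-90	NA	NA	0.25
HIS	-65	-70	NA	NA	0.45
HIS	-177	65	NA	NA	0.30
HIS	62	-85	NA	NA	0.25
ASP	-70	-15	NA	NA	0.51
ASP	-170	0	NA	NA	0.29
ASP	62	0	NA	NA	0.20
ASN	-65	-20	NA	NA	0.45
ASN	-174	0	NA	NA	0.30
ASN	62	0	NA	NA	0.25
GLU	-67	180	-10	NA	0.35
GLU	-177	180	0	NA	0.30
GLU	-65	-65	-40	NA	0.20
GLU	62	180	0	NA	0.15
GLN	-67	180	-25	NA	0.35
GLN	-177	180	0	NA	0.30
GLN	-65	-65	-40	NA	0.20
GLN	62	180	0	NA	0.15
LYS	-67	180	180	180	0.30
LYS	180	180	180	180	0.25
LYS	-60	-68	180	180	0.20
LYS	-67	180	-68	180	0.15
LYS	62	180	180	180	0.10
ARG	-67	180	180	180	0.25
ARG	180	180	180	180	0.20
ARG	-67	-167	180	180	0.20
ARG	-67	-65	-65	-85	0.20
ARG	62	180	180	85	0.15
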