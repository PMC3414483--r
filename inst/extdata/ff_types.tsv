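type	epsilon	rmin2	gb_radius	gb_screen
CT	0.1094	1.908	1.7	0.72
CR	0.086	1.908	1.7	0.72
C	0.086	1.908	1.7	0.72
N	0.17	1.824	1.55	0.79
N3	0.17	1.824	1.55	0.79
O	0.21	1.6612	1.5	0.85
OH	0.2104	1.721	1.5	0.85
O2	0.21	1.6612	1.5	0.85
S	0.25	2	1.8	0.96
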