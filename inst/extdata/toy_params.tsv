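# Per-atom force-field parameters for the synthetic receptor (RCP) and
# peptide (LIG) residues: partial charge (e), Lennard-Jones well depth
# (kcal/mol) and half r_min (A), intrinsic Born radius (A). Values sit in
# common protein force-field ranges. Column charge sums to -1.86.
residue_name	atom_name	charge	lj_epsilon	lj_rmin_half	gb_radius
RCP	N	-0.47	0.20	1.85	1.55
RCP	CA	0.07	0.11	2.06	1.70
RCP	C	0.51	0.11	2.00	1.70
RCP	O	-0.51	0.12	1.70	1.50
RCP	NZ	-0.30	0.20	1.85	1.55
LIG	N	-0.47	0.20	1.85	1.55
LIG	CA	0.07	0.11	2.06	1.70
LIG	C	0.51	0.11	2.00	1.70
LIG	O	-0.51	0.12	1.70	1.50
LIG	OE1	-0.76	0.12	1.70	1.50
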