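# Steady-state kinetics of PKA-catalysed phosphorylation of Kemptide
# (LRRASLG) and derivatives: maximal rate vmax in umol/(min mg), apparent
# Michaelis constant km in uM. The serine at position 21 (position 0) is the
# phosphoacceptor. is_reference flags the wild-type peptide.
peptide	vmax	km	is_reference
LRRASLG	20.2	16.0	1
LARASLG	8.7	4900.0	0
LRAASLG	5.3	6300.0	0
LKRASLG	17.1	1400.0	0
LRKASLG	16.9	260.0	0
LHRASLG	12.1	415.0	0
LRHASLG	6.5	1340.0	0
RRASLG	17.9	26.0	0
RASLG	10.2	4400.0	0
LRRASL	18.1	57.0	0
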