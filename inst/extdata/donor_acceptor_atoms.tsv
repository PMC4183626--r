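# Heavy atoms allowed to donate/accept hydrogen bonds. residue_name "*"
# wildcards any residue; atoms not listed fall back to element defaults
# (N donor, O acceptor). Edit or replace via donor_acceptor_table(path=).
residue_name	atom_name	role
*	N	donor
*	O	acceptor
*	OG	both
*	OG1	both
*	OH	both
*	OD1	acceptor
*	OD2	acceptor
*	OE1	acceptor
*	OE2	acceptor
*	NE	donor
*	NH1	donor
*	NH2	donor
*	NZ	donor
*	ND1	both
*	NE2	both
*	O3'	both
*	O1G	acceptor
*	O2G	acceptor
*	O3G	acceptor
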