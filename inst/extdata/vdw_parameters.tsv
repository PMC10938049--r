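# Per-element van der Waals parameters used by assign_parameters().
# radius: Bondi van der Waals radius, Angstrom.
# well_depth: Lennard-Jones well depth of Amber/GAFF magnitude, kcal/mol.
# The "default" row is applied to elements not listed (lookup is total).
element	radius	well_depth
C	1.70	0.0860
N	1.55	0.1700
O	1.52	0.2100
S	1.80	0.2500
H	1.20	0.0157
P	1.80	0.2000
default	1.70	0.1000
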