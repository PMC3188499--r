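# Atom-type parameters for the nonbonded model.
# radius: per-atom contribution to the pair minimum-energy distance (A);
# eps: Lennard-Jones well depth (energy units); dgfree: solvation free
# energy of the exposed atom (negative = prefers water, so burial is
# penalised); vol: solvation volume (A^3).
type	radius	eps	dgfree	vol
CAli	1.85	0.12	0.90	14.0
CAro	1.82	0.13	0.70	12.0
CPol	1.80	0.08	0.00	10.0
NAmide	1.65	0.17	-5.5	9.0
NPos	1.65	0.17	-12.0	9.0
OCarb	1.52	0.19	-5.0	11.0
OCoo	1.52	0.19	-9.0	11.0
OHyd	1.54	0.19	-5.5	11.0
S	1.95	0.28	0.20	15.5
P	1.90	0.30	-3.0	15.0
XOther	1.70	0.10	0.00	10.0
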