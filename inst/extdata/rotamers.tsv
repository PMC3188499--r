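# Coarse backbone-independent rotamer library.
# Format: residue <TAB> per-chi candidate angles (degrees); chi levels are
# separated by ';', candidates within a level by ','. The library expands to
# the full grid of combinations. ALA/GLY carry the empty tuple. Users may
# substitute their own file via loadRotamerLibrary(path).
ALA
GLY
SER	-60,180,60
CYS	-60,180,60
THR	-60,180,60
VAL	180,-60,60
PRO	25,-25;-35,35
LEU	-60,180,60;180,60,-60
ILE	-60,180,60;180,-60,60
MET	-60,180,60;180,-60,60;180,-60,60
PHE	-60,180,60;90,-30
TYR	-60,180,60;90,-30
TRP	-60,180,60;90,-90,-5
HIS	-60,180,60;90,-90,-75
ASP	-60,180,60;0,60
ASN	-60,180,60;0,90,180,-90
GLN	-60,180,60;180,-60,60;0,90,180,-90
GLU	-60,180,60;180,-60,60;0,60
LYS	-60,180,60;180,-60,60;180,-60,60;180,-60,60
ARG	-60,180,60;180,-60,60;180,-60,60;180,-90,90
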