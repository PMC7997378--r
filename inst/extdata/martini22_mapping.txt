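# Martini 2.2-style protein mapping: heavy atoms -> beads, one backbone bead
# per residue plus 0-4 side-chain beads. Editable: columns are residue name,
# bead label, comma-separated member atom names (PDB conventions). Terminal
# OXT and terminal amide hydrogens fold into the backbone bead.
# res  bead  atoms
ALA  BB   N,CA,C,O,CB
GLY  BB   N,CA,C,O
VAL  BB   N,CA,C,O
VAL  SC1  CB,CG1,CG2
LEU  BB   N,CA,C,O
LEU  SC1  CB,CG,CD1,CD2
ILE  BB   N,CA,C,O
ILE  SC1  CB,CG1,CG2,CD1
PRO  BB   N,CA,C,O
PRO  SC1  CB,CG,CD
MET  BB   N,CA,C,O
MET  SC1  CB,CG,SD,CE
CYS  BB   N,CA,C,O
CYS  SC1  CB,SG
SER  BB   N,CA,C,O
SER  SC1  CB,OG
THR  BB   N,CA,C,O
THR  SC1  CB,OG1,CG2
ASN  BB   N,CA,C,O
ASN  SC1  CB,CG,OD1,ND2
GLN  BB   N,CA,C,O
GLN  SC1  CB,CG,CD,OE1,NE2
ASP  BB   N,CA,C,O
ASP  SC1  CB,CG,OD1,OD2
GLU  BB   N,CA,C,O
GLU  SC1  CB,CG,CD,OE1,OE2
LYS  BB   N,CA,C,O
LYS  SC1  CB,CG,CD
LYS  SC2  CE,NZ
ARG  BB   N,CA,C,O
ARG  SC1  CB,CG,CD
ARG  SC2  NE,CZ,NH1,NH2
HIS  BB   N,CA,C,O
HIS  SC1  CB,CG
HIS  SC2  ND1,CE1
HIS  SC3  CD2,NE2
PHE  BB   N,CA,C,O
PHE  SC1  CB,CG
PHE  SC2  CD1,CE1
PHE  SC3  CD2,CE2,CZ
TYR  BB   N,CA,C,O
TYR  SC1  CB,CG
TYR  SC2  CD1,CE1
TYR  SC3  CD2,CE2,CZ,OH
TRP  BB   N,CA,C,O
TRP  SC1  CB,CG
TRP  SC2  CD1,NE1
TRP  SC3  CD2,CE2,CE3
TRP  SC4  CZ2,CZ3,CH2
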