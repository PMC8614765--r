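resname,role,atom,hydrogens,group
*,donor,N,H,N
SER,donor,OG,HG1|HG,OG
THR,donor,OG1,HG1,OG1
TYR,donor,OH,HH,OH
CYS,donor,SG,HG1|HG,SG
TRP,donor,NE1,HE1,NE1
ASN,donor,ND2,HD21|HD22,ND2
GLN,donor,NE2,HE21|HE22,NE2
LYS,donor,NZ,HZ1|HZ2|HZ3,NZ
ARG,donor,NE,HE,NE
ARG,donor,NH1,HH11|HH12,NH
ARG,donor,NH2,HH21|HH22,NH
HIS,donor,ND1,HD1,ND1
HIS,donor,NE2,HE2,NE2
*,acceptor,O,,O
*,acceptor,OXT,,O
ASP,acceptor,OD1,,OD
ASP,acceptor,OD2,,OD
GLU,acceptor,OE1,,OE
GLU,acceptor,OE2,,OE
ASN,acceptor,OD1,,OD1
GLN,acceptor,OE1,,OE1
SER,acceptor,OG,,OG
THR,acceptor,OG1,,OG1
TYR,acceptor,OH,,OH
HIS,acceptor,ND1,,ND1
HIS,acceptor,NE2,,NE2
MET,acceptor,SD,,SD
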