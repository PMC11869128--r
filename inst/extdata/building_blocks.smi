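CN
CCN
CC(C)N
NCc1ccccc1
Nc1ccccc1
Nc1ccc(F)cc1
C1CCNCC1
C1COCCN1
CNC
NCCO
NCCc1ccccc1
Nc1cccnc1
CC(=O)O
CCC(=O)O
OC(=O)c1ccccc1
OC(=O)c1cccnc1
OC(=O)Cc1ccccc1
OC(=O)C1CC1
O=Cc1ccccc1
CN(C)c1ccc(C=O)cc1
O=Cc1ccco1
CC=O
CCC=O
O=Cc1cccnc1
CS(=O)(=O)Cl
O=S(=O)(Cl)c1ccccc1
Cc1ccc(cc1)S(=O)(=O)Cl
CCBr
CCCBr
BrCc1ccccc1
CCI
CCO
CC(C)O
OCc1ccccc1
OCCc1ccccc1
O=C=Nc1ccccc1
CCN=C=O
Brc1ccccc1
Ic1ccc(C)cc1
Fc1ccc(cn1)C
Fc1ccc(cc1)C#N
OB(O)c1ccccc1
OB(O)c1ccc(F)cc1
OB(O)c1cccnc1
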