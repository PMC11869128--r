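# Robot-amenable reaction templates for the genetic generator.
# Columns: name<TAB>reaction SMARTS (molecule is reactant 1, partner building
# block is reactant 2 for arity-2 templates)<TAB>arity<TAB>react1 SMARTS
# (compatibility pattern for the molecule)<TAB>react2 SMARTS (pattern a
# partner block must match)<TAB>reversible.
amide_coupling_acid	[CX3:1](=[OX1:2])[OX2H1].[NX3;H2,H1;!$(N[C,S]=[O,S,N]):3]>>[CX3:1](=[OX1:2])[NX3:3]	2	[CX3](=O)[OX2H1]	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	1
amide_coupling_amine	[NX3;H2,H1;!$(N[C,S]=[O,S,N]):3].[CX3:1](=[OX1:2])[OX2H1]>>[CX3:1](=[OX1:2])[NX3:3]	2	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	[CX3](=O)[OX2H1]	1
sulfonamide_formation	[NX3;H2,H1;!$(N[C,S]=[O,S,N]):1].[SX4:2](=[OX1:3])(=[OX1:4])[Cl]>>[NX3:1][SX4:2](=[OX1:3])(=[OX1:4])	2	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	[SX4](=O)(=O)[Cl]	1
reductive_amination	[NX3;H2,H1;!$(N[C,S]=[O,S,N]):1].[CX3H1:2]=[OX1]>>[NX3:1][CX4H2:2]	2	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	[CX3H1]=[OX1]	1
n_alkylation	[NX3;H2,H1;!$(N[C,S]=[O,S,N]):1].[CX4:2][Cl,Br,I]>>[NX3:1][CX4:2]	2	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	[CX4][Cl,Br,I]	1
ester_formation	[CX3:1](=[OX1:2])[OX2H1].[OX2H1:3][CX4:4]>>[CX3:1](=[OX1:2])[OX2:3][CX4:4]	2	[CX3](=O)[OX2H1]	[OX2H1][CX4]	1
urea_formation	[NX3;H2,H1;!$(N[C,S]=[O,S,N]):1].[NX2:2]=[CX2:3]=[OX1:4]>>[NX3:1][CX3:3](=[OX1:4])[NX3H1:2]	2	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	[NX2]=C=[OX1]	1
snar_amination	[NX3;H2,H1;!$(N[C,S]=[O,S,N]):1].[cX3:2][F]>>[NX3:1][cX3:2]	2	[NX3;H2,H1;!$(N[C,S]=[O,S,N])]	[cX3][F]	1
imine_condensation	[NX3;H2;!$(N[C,S]=[O,S,N]):1].[CX3H1:2]=[OX1]>>[NX2:1]=[CX3H1:2]	2	[NX3;H2;!$(N[C,S]=[O,S,N])]	[CX3H1]=[OX1]	1
suzuki_biaryl	[c:1][Br,I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]	2	[c][Br,I]	[c][BX3]([OX2H])[OX2H]	1
williamson_ether	[OX2H1:1].[CX4:2][Cl,Br,I]>>[OX2:1][CX4:2]	2	[OX2H1]	[CX4][Cl,Br,I]	1
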