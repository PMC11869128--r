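# Default substructure filter catalog: hydroxamate (deliberately excluded
# zinc binder), a curated set of PAINS-type frequent hitters, and reactive
# groups unsuited to automated handling.  Format: name<TAB>SMARTS.
hydroxamate	[CX3](=O)[NX3][OX2]
pains_quinone_para	O=C1C=CC(=O)C=C1
pains_quinone_ortho	O=C1C(=O)C=CC=C1
pains_catechol	[OX2H]c1ccccc1[OX2H]
pains_rhodanine	O=C1CSC(=S)N1
pains_azo_aryl	cN=Nc
pains_nitroso	[#6][NX2]=[OX1]
pains_imine_one	C=C1C(=O)NC(=O)NC1=O
reactive_acyl_halide	[CX3](=O)[F,Cl,Br,I]
reactive_anhydride	[CX3](=O)O[CX3](=O)
reactive_isocyanate	[NX2]=C=[OX1]
reactive_isothiocyanate	[NX2]=C=[SX1]
reactive_epoxide	C1OC1
reactive_aziridine	C1NC1
reactive_peroxide	[OX2][OX2]
reactive_diazonium	[N+]#N
reactive_michael_nitrile	C=C[CX2]#N
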