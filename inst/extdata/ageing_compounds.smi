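# Twelve ageing-related test compounds (well-known structures).
# Format: SMILES<TAB>id
CC1CCC2CC(C(=CC=CC=CC(CC(C(=O)C(C(C(=CC(C(=O)CC(OC(=O)C3CCCCN3C(=O)C(=O)C1(O)O2)C(C)CC4CCC(O)C(C4)OC)C)C)O)OC)C)C)C)OC	rapamycin
OCC(O)C1OC(=O)C(O)=C1O	vitamin_C
CC1=C(C(C)(C)CCC1)/C=C/C(C)=C/C=C/C(C)=C/CO	retinol
CC1=C(C(C)(C)CCC1)/C=C/C(C)=C/C=C/C(C)=C/C(=O)O	retinoic_acid
Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1	resveratrol
CN(C)C(=N)N=C(N)N	metformin
CC(=O)Oc1ccccc1C(=O)O	acetylsalicylic_acid
Oc1ccccc1C(=O)O	salicylic_acid
CCCCCCCC(=O)c1ccc(O)c(C(=O)O)c1	C8_SA
CCCCCCCCCCCC(=O)c1ccc(O)c(C(=O)O)c1	C12_SA
CCCCCC1C(O)CCC1CC(=O)O	LR2412
OCC(O)CC1OCC(O)C(O)C1O	C_xyloside
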