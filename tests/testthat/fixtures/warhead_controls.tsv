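name	positive_smiles	negative_smiles
acrylamide	C=CC(=O)Nc1ccccc1	CCC(=O)Nc1ccccc1
propiolamide	C#CC(=O)Nc1ccccc1	C=CC(=O)OC
vinyl sulfone	C=CS(=O)(=O)c1ccccc1	CCS(=O)(=O)c1ccccc1
haloacetyl	ClCC(=O)Nc1ccccc1	CCC(=O)Nc1ccccc1
epoxide	C1OC1Cc1ccccc1	OCCOc1ccccc1
aziridine	C1CN1Cc1ccccc1	CN(C)Cc1ccccc1
maleimide	O=C1C=CC(=O)N1c1ccccc1	O=C1CCC(=O)N1c1ccccc1
aldehyde	O=Cc1ccccc1	OCc1ccccc1
nitrile	N#Cc1ccccc1	CCNc1ccccc1
boronic acid	OB(O)c1ccccc1	OCC(O)c1ccccc1
beta-lactam	O=C1CCN1c1ccccc1	O=C1CCCN1c1ccccc1
sulfonyl fluoride	FS(=O)(=O)c1ccccc1	CS(=O)(=O)c1ccccc1
heterocyclic urea	O=C1NCCN1c1ccccc1	CNC(=O)Nc1ccccc1
haloheteroarene	Clc1ccccn1	Clc1ccccc1
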