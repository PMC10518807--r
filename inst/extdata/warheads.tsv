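name	smarts	residues
acrylamide	[CX3;!R;H2]=[CX3;!R]C(=O)[NX3]	Cys;Lys;Ser;Thr
propiolamide	[CX2]#[CX2]C(=O)[NX3]	Cys
vinyl sulfone	[CX3;!R]=[CX3;!R][SX4](=O)(=O)	Cys
haloacetyl	[Cl,Br,I][CX4;H2][CX3]=O	Cys
epoxide	C1OC1	Cys;Asp;Glu
aziridine	C1NC1	Cys;Asp;Glu
maleimide	O=C1C=CC(=O)N1	Cys
aldehyde	[CX3H1](=O)[#6]	Cys;Ser;Lys
nitrile	[CX2]#[NX1]	Cys;Ser
boronic acid	[BX3]([OX2])[OX2]	Ser
beta-lactam	O=C1[#6][#6]N1	Ser
sulfonyl fluoride	[SX4](=O)(=O)F	Ser;Thr;Tyr;Lys
heterocyclic urea	O=[CX3;R]([NX3;R])[NX3;R]	Ser;Thr
haloheteroarene	[F,Cl][$(c:n)]	Cys
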