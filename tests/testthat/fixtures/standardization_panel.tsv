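input_smiles	expected_inchi
CC(=O)Oc1ccccc1C(=O)O	InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)
CC(=O)Oc1ccccc1C(=O)[O-].[Na+]	InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)
CC(C)Cc1ccc(cc1)[C@@H](C)C(=O)O	InChI=1S/C13H18O2/c1-9(2)8-11-4-6-12(7-5-11)10(3)13(14)15/h4-7,9-10H,8H2,1-3H3,(H,14,15)
CC(C)Cc1ccc(cc1)C(C)C(=O)[O-]	InChI=1S/C13H18O2/c1-9(2)8-11-4-6-12(7-5-11)10(3)13(14)15/h4-7,9-10H,8H2,1-3H3,(H,14,15)
C[C@H](N)C(=O)O	InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)
C[C@@H](N)C(=O)O.Cl	InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)
NCC(=O)O	InChI=1S/C2H5NO2/c3-1-2(4)5/h1,3H2,(H,4,5)
[NH3+]CC(=O)[O-]	InChI=1S/C2H5NO2/c3-1-2(4)5/h1,3H2,(H,4,5)
CCN(CC)CC.Cl	InChI=1S/C6H15N/c1-4-7(5-2)6-3/h4-6H2,1-3H3
CC[NH+](CC)CC.[Cl-]	InChI=1S/C6H15N/c1-4-7(5-2)6-3/h4-6H2,1-3H3
OC(=O)c1ccccc1	InChI=1S/C7H6O2/c8-7(9)6-4-2-1-3-5-6/h1-5H,(H,8,9)
[O-]C(=O)c1ccccc1.[Na+]	InChI=1S/C7H6O2/c8-7(9)6-4-2-1-3-5-6/h1-5H,(H,8,9)
C1CC1C(=O)[O-]	InChI=1S/C4H6O2/c5-4(6)3-1-2-3/h3H,1-2H2,(H,5,6)
c1ccc(cc1)S(=O)(=O)[O-].[Na+]	InChI=1S/C6H6O3S/c7-10(8,9)6-4-2-1-3-5-6/h1-5H,(H,7,8,9)
Cc1ccc(cc1)S(=O)(=O)O	InChI=1S/C7H8O3S/c1-6-2-4-7(5-3-6)11(8,9)10/h2-5H,1H3,(H,8,9,10)
NC(=O)c1ccccc1	InChI=1S/C7H7NO/c8-7(9)6-4-2-1-3-5-6/h1-5H,(H2,8,9)
CN(C)CCOC(c1ccccc1)c1ccccc1.Cl	InChI=1S/C17H21NO/c1-18(2)13-14-19-17(15-9-5-3-6-10-15)16-11-7-4-8-12-16/h3-12,17H,13-14H2,1-2H3
CN(C)CC/C=C(/c1ccccc1)c1ccc(C)cc1	InChI=1S/C19H23N/c1-16-11-13-18(14-12-16)19(10-7-15-20(2)3)17-8-5-4-6-9-17/h4-6,8-14H,7,15H2,1-3H3
F/C=C/C(=O)O	InChI=1S/C3H3FO2/c4-2-1-3(5)6/h1-2H,(H,5,6)
F/C=C\C(=O)O	InChI=1S/C3H3FO2/c4-2-1-3(5)6/h1-2H,(H,5,6)
C[N+](C)(C)CCO	InChI=1S/C5H14NO/c1-6(2,3)4-5-7/h7H,4-5H2,1-3H3/q+1
C[N+](C)(C)CCO.[Cl-]	InChI=1S/C5H14NO/c1-6(2,3)4-5-7/h7H,4-5H2,1-3H3/q+1
c1ccc(cc1)[N+](=O)[O-]	InChI=1S/C6H5NO2/c8-7(9)6-4-2-1-3-5-6/h1-5H
Cc1ccccc1[N+](=O)[O-]	InChI=1S/C7H7NO2/c1-6-4-2-3-5-7(6)8(9)10/h2-5H,1H3
OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O	InChI=1S/C6H12O6/c7-1-2-3(8)4(9)5(10)6(11)12-2/h2-11H,1H2
N[C@@H](Cc1ccccc1)C(=O)O	InChI=1S/C9H11NO2/c10-8(9(11)12)6-7-4-2-1-3-5-7/h1-5,8H,6,10H2,(H,11,12)
N[C@@H](Cc1ccccc1)C(=O)[O-].[Na+]	InChI=1S/C9H11NO2/c10-8(9(11)12)6-7-4-2-1-3-5-7/h1-5,8H,6,10H2,(H,11,12)
CC(=O)NC1=CC=C(C=C1)O	InChI=1S/C8H9NO2/c1-6(10)9-7-2-4-8(11)5-3-7/h2-5,11H,1H3,(H,9,10)
Oc1ccc(cc1)C(=O)OCC	InChI=1S/C9H10O3/c1-2-12-9(11)7-3-5-8(10)6-4-7/h3-6,10H,2H2,1H3
CCOC(=O)c1ccccc1N	InChI=1S/C9H11NO2/c1-2-12-9(11)7-5-3-4-6-8(7)10/h3-6H,2,10H2,1H3
NCCc1ccc(O)c(O)c1.Cl	InChI=1S/C8H11NO2/c9-4-3-6-1-2-7(10)8(11)5-6/h1-2,5,10-11H,3-4,9H2
OC(=O)CC(O)(CC(=O)O)C(=O)O	InChI=1S/C6H8O7/c7-3(8)1-6(13,5(11)12)2-4(9)10/h13H,1-2H2,(H,7,8)(H,9,10)(H,11,12)
OC(=O)/C=C/C(=O)O	InChI=1S/C4H4O4/c5-3(6)1-2-4(7)8/h1-2H,(H,5,6)(H,7,8)
OC(=O)/C=C\C(=O)O	InChI=1S/C4H4O4/c5-3(6)1-2-4(7)8/h1-2H,(H,5,6)(H,7,8)
CN1CCC[C@H]1c1cccnc1	InChI=1S/C10H14N2/c1-12-7-3-5-10(12)9-4-2-6-11-8-9/h2,4,6,8,10H,3,5,7H2,1H3
CN1CCC[C@@H]1c1cccnc1.Cl	InChI=1S/C10H14N2/c1-12-7-3-5-10(12)9-4-2-6-11-8-9/h2,4,6,8,10H,3,5,7H2,1H3
OCC(O)CO	InChI=1S/C3H8O3/c4-1-3(6)2-5/h3-6H,1-2H2
CC(=O)[O-].CC(=O)[O-].[Ca+2]	InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)
Nc1ncnc2n(cnc12)[C@@H]1O[C@H](CO)[C@@H](O)[C@H]1O	InChI=1S/C10H13N5O4/c11-8-5-9(13-2-12-8)15(3-14-5)10-7(18)6(17)4(1-16)19-10/h2-4,6-7,10,16-18H,1H2,(H2,11,12,13)
CC(C)(C)NC[C@H](O)c1ccc(O)c(CO)c1	InChI=1S/C13H21NO3/c1-13(2,3)14-7-12(17)9-4-5-11(16)10(6-9)8-15/h4-6,12,14-17H,7-8H2,1-3H3
c1ccc2c(c1)cccn2	InChI=1S/C9H7N/c1-2-6-9-8(4-1)5-3-7-10-9/h1-7H
c1cc[nH+]cc1.[Cl-]	InChI=1S/C5H5N/c1-2-4-6-5-3-1/h1-5H
OC(=O)c1cc(O)c(O)c(O)c1	InChI=1S/C7H6O5/c8-4-1-3(7(11)12)2-5(9)6(4)10/h1-2,8-10H,(H,11,12)
COc1cc(CC=C)ccc1O	InChI=1S/C10H12O2/c1-3-4-8-5-6-9(11)10(7-8)12-2/h3,5-7,11H,1,4H2,2H3
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	InChI=1S/C14H22N2O3/c1-10(2)16-8-12(17)9-19-13-5-3-11(4-6-13)7-14(15)18/h3-6,10,12,16-17H,7-9H2,1-2H3,(H2,15,18)
CSCC[C@H](N)C(=O)O	InChI=1S/C5H11NO2S/c1-9-3-2-4(6)5(7)8/h4H,2-3,6H2,1H3,(H,7,8)
OS(=O)(=O)c1ccc2ccccc2c1	InChI=1S/C10H8O3S/c11-14(12,13)10-6-5-8-3-1-2-4-9(8)7-10/h1-7H,(H,11,12,13)
NS(=O)(=O)c1ccc(N)cc1	InChI=1S/C6H8N2O2S/c7-5-1-3-6(4-2-5)11(8,9)10/h1-4H,7H2,(H2,8,9,10)
CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O	InChI=1S/C16H18N2O4S/c1-16(2)12(15(21)22)18-13(20)11(14(18)23-16)17-10(19)8-9-6-4-3-5-7-9/h3-7,11-12,14H,8H2,1-2H3,(H,17,19)(H,21,22)
CN1C(=O)N(C)c2ncn(C)c2C1=O	InChI=1S/C8H10N4O2/c1-10-4-9-6-5(10)7(13)12(3)8(14)11(6)2/h4H,1-3H3
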