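id,smiles,functional_class,available
A01,Cc1ccccc1N,amine,1
A02,COc1cccc(N)c1C,amine,1
A03,Cc1cccc(N)c1C,amine,1
A04,FC(F)(F)c1cccc(N)c1C,amine,1
A05,Clc1cccc(N)c1C,amine,1
A06,Cc1cccc(C)c1N,amine,1
A07,Nc1ccccc1Cl,amine,1
A08,N,amine,1
A09,CN,amine,1
A10,NCc1c(Cl)cccc1Cl,amine,1
A11,COc1cccc(OC)c1CN,amine,1
A12,CNCc1c(Cl)cccc1Cl,amine,1
A13,C1CCNC1,amine,1
A14,Nc1ccccc1,amine,1
C01,CC(=O)Cl,acyl_chloride,1
C02,OCC(=O)Cl,acyl_chloride,1
C03,O=C(Cl)Cc1ccccc1,acyl_chloride,1
C04,CC(C)CC(=O)Cl,acyl_chloride,1
C05,O=C(Cl)C1CC1,acyl_chloride,1
C06,CC(C)C(=O)Cl,acyl_chloride,1
C07,O=C(Cl)Cc1ccc(Cl)cc1,acyl_chloride,1
C08,O=C(Cl)C1CCCCC1,acyl_chloride,1
C09,CCC(=O)Cl,acyl_chloride,1
S01,O=S(=O)(Cl)c1ccccc1,sulfonyl_chloride,1
S02,CS(=O)(=O)Cl,sulfonyl_chloride,1
B01,OB(O)c1ccccc1,aryl_boronic_acid,1
H01,Brc1ccccc1,aryl_halide,1
H02,Clc1ccccn1,heteroaryl_halide,1
K01,CC=O,carbonyl,1
K02,O=Cc1ccccc1,carbonyl,1
P01,Oc1ccccc1,phenol,1
X01,BrCc1ccccc1,alkyl_halide,1
X02,CBr,alkyl_halide,1
Y01,C#Cc1ccccc1,alkyne,1
Z01,[N-]=[N+]=Nc1ccccc1,azide,1
N01,N#Cc1ccccc1,nitrile,1
D01,Nc1ccccc1N,aryl_diamine,1
D02,Nc1ccccc1O,aminophenol,1
D03,Nc1ccccc1S,aminothiophenol,1
T01,CC(N)=S,thioamide,1
Q01,CC(=O)CBr,bromoketone,1
G01,NNc1ccccc1,hydrazine,1
G02,CC(=O)CC(C)=O,diketone_13,1
G03,O=C(c1ccccc1)C(=O)c1ccccc1,diketone_12,1
G04,CC(=O)CCC(C)=O,diketone_14,1
G05,CC(=O)NN,hydrazide,1
G06,CC(N)=NO,amidoxime,1
G07,CC(N)=N,amidine,1
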