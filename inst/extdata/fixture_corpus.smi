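CCCCC
CCC
Oc1ccccc1O
CCCO
c1ccccc1
CCOCC
CCCCCCCC
c1ccccc1
CCCCC(C)C
CCc1ccccc1
C1CCCC1N
CCC(C)C
C1CCCCC1
C1CCCC1
CCC(=O)OC
C1CCCC1
CC(=O)O
CCCOCCC
C1CCCCC1
C1CCCCC1
CCO
CC(C)C
C1CCCC1
CCC(=O)OCCC
CCCCC
CC
C1CCCCC1
c1ccccc1
CCC(=O)C
c1ccccc1
C1CCCC1
CCN
CCN
CCCC(=O)O
COCCC
CCCO
CCCCO
Cc1ccccc1
CCN
CN
C1CCCCC1C
c1ccccc1
C1CCCC1
C1CCCC1
C1CCCC1
CC(=O)O
C1CCCC1N
CCCCC#N
CCCCCN
CCCCN
CCC(C)C
CCC(C)C
CCc1ccccc1
CCCOC
CCCC#N
C1CCCC1N
CCC
CCC(=O)OCC
CC(=O)C
c1ccccc1
CCC(=O)O
CCCC(=O)CC
CC#N
CCC(C)C
c1ccccc1
CCCCN
c1ccccc1
CCCCCC
CCCCCC
CCOCC
c1ccccc1
C1CCCCC1
C1CCCCC1
CCCCOCC
CCC(=O)C
CC(=O)CC
CC(C)C
CCCCCCC
C1CCCCC1C
CCCCCN
CCCCCC(C)C
C1CCCC1N
CCC(=O)OC
CCCCOCCCC
CCC(=O)CCC
CCC(=O)O
CC
CC(=O)O
CCCC(C)C
C1CCCC1
CO
Oc1ccccc1
CCN
CCC(C)C
c1ccccc1
CCN
CCCN
C1CCCCC1
CCCC(=O)O
Oc1ccccc1C
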