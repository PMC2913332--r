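# Small hand-checkable molecules used in examples and tests.
# format: SMILES <whitespace> identifier
CCO ethanol
CCC propane
CCCC n-butane
CC(C)C isobutane
CC(C)(C)C neopentane
C1CCCCC1 cyclohexane
c1ccccc1 benzene
Cc1ccccc1 toluene
Oc1ccccc1 phenol
Nc1ccccc1 aniline
c1ccncc1 pyridine
c1cc[nH]c1 pyrrole
c1ccoc1 furan
c1ccsc1 thiophene
Clc1ccccc1 chlorobenzene
[O-][N+](=O)c1ccccc1 nitrobenzene
c1ccc2ccccc2c1 naphthalene
C=Cc1ccccc1 styrene
CC(=O)C acetone
CC(=O)O acetic_acid
C=CC=O acrolein
C=CC=C 1,3-butadiene
CC(=C)C=C isoprene
CC#N acetonitrile
CSC dimethyl_sulfide
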