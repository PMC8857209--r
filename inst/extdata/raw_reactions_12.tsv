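rxn_smiles	ec	source
CC(=O)O.OCC>>CC(=O)OCC.O	3.1.1.1	alphadb
CC(=O)O.OCC>>CC(=O)OCC.O	3.1.1.1	betadb
CCCO>>CCC=O.OP(=O)(O)O	1.1.1.1	alphadb
CC(=O)OCC.O>>CC(=O)O.OCC	3.1.1.2	gammadb
OCCO>>O=CCO.O=CC=O	1.1.3.1	alphadb
CCO>>O	1.1.1.5	betadb
CC(=O)O.NCCC>>CC(=O)NCCC.NCCC	6.3.2.1	gammadb
O=CCC.NCC(=O)O>>NCCC	2.6.1.1	alphadb
O=CCC.NCC(=O)O>>NCCC	2.6.1.2	deltadb
OCCC>>O=CCC	1.1.2.3	betadb
OC(=O)CCC(=O)O>>CCC(=O)O.O=C=O	4.1.1.2	alphadb
C1CC>>CC	5.3.1.1	gammadb
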