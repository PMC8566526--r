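name	smarts
para_quinone	O=C1C=CC(=O)C=C1
ortho_quinone	O=C1C(=O)C=CC=C1
quinone_methide	C=C1C=CC(=O)C=C1
rhodanine	S=C1NC(=O)CS1
aromatic_azo	cN=Nc
isothiazolinone	O=C1C=CSN1
hydrazone	C=NN
acyl_halide	C(=O)[Cl,Br,I]
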