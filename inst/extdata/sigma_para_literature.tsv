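# Experimental Hammett sigma-para and Hansch-Fujita pi substituent constants
# for classic mono-substituted benzene substituents, transcribed from the
# standard medicinal-chemistry compilations (Hansch-Leo-Taft tables).
# Columns: attachment-marked SMILES, sigma-para, pi (octanol-water).
smiles	sigma_exp	pi_exp
[*][H]	0.00	0.00
[*]C	-0.17	0.56
[*]CC	-0.15	1.02
[*]CCC	-0.13	1.55
[*]C(C)C	-0.15	1.53
[*]C(C)(C)C	-0.20	1.98
[*]c1ccccc1	-0.01	1.96
[*]F	0.06	0.14
[*]Cl	0.23	0.71
[*]Br	0.23	0.86
[*]I	0.18	1.12
[*]C(F)(F)F	0.54	0.88
[*]OC	-0.27	-0.02
[*]OCC	-0.24	0.38
[*]O	-0.37	-0.67
[*]N	-0.66	-1.23
[*]N(C)C	-0.83	0.18
[*][N+](=O)[O-]	0.78	-0.28
[*]C#N	0.66	-0.57
[*]C(=O)C	0.50	-0.55
[*]C=O	0.42	-0.65
[*]C(=O)O	0.45	-0.32
[*]C(=O)N	0.36	-1.49
[*]C(=O)OC	0.45	-0.01
[*]S(C)(=O)=O	0.72	-1.63
[*]SC	0.00	0.61
[*]OC(F)(F)F	0.35	1.04
[*]NC(C)=O	0.00	-0.97
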