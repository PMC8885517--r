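name	C	H	N	O	S	labeled_dN
Carbamidomethyl	2	3	1	1	0	0
Acetyl	2	2	0	1	0	0
Oxidation	0	0	0	1	0	0
Gln->pyro-Glu	0	-3	-1	0	0	-1
Met-loss	-5	-9	-1	-1	-1	-1
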