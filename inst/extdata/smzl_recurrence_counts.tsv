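site	assay	n_mutated_discovery	n_discovery	n_mutated_validation	n_validation
MYD88_T794C	pyrosequencing	1	2	3	24
NOTCH2_C7310T	pyrosequencing	1	2	0	24
SMYD1_G839T	pyrosequencing	1	2	0	24
ZNF608_A3659G	pyrosequencing	1	2	0	24
PDE10A_G1072A	pyrosequencing	1	2	0	24
SMYD1_coding	sanger	1	2	2	8
NOTCH2_PEST	sanger	1	2	0	8
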