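# Residue-level coarse-grained bead parameters, schema v1.
# code: one-letter amino-acid code (X = phosphoserine)
# mass: amu; charge: elementary charges (His neutral, termini uncharged)
# sigma: contact diameter, Angstrom; lambda: hydrophobicity stickiness in [0, 1]
# lambda follows the Tesei et al. CALVADOS-family calibration of the HPS scale;
# sigma are the standard residue van der Waals diameters of the HPS lineage.
code	mass	charge	sigma	lambda
A	71.0788	0	5.04	0.2743
R	156.1875	1	6.56	0.7307
N	114.1038	0	5.68	0.4255
D	115.0886	-1	5.58	0.0416
C	103.1388	0	5.48	0.5615
Q	128.1307	0	6.02	0.3934
E	129.1155	-1	5.92	0.0007
G	57.0519	0	4.50	0.7058
H	137.1411	0	6.08	0.4663
I	113.1594	0	6.18	0.5423
L	113.1594	0	6.18	0.6440
K	128.1741	1	6.36	0.1790
M	131.1926	0	6.18	0.5308
F	147.1766	0	6.36	0.8672
P	97.1167	0	5.56	0.3593
S	87.0782	0	5.18	0.4625
T	101.1051	0	5.62	0.3713
W	186.2132	0	6.78	0.9893
Y	163.1760	0	6.46	0.9774
V	99.1326	0	5.86	0.2083
X	167.0582	-1	5.18	0.4625
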