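# Amino-acid property scales used for type-2 pseudo amino acid composition.
# fixture v1. Sources: hydrophobicity — the scale used in Chou's original
# PseAAC work (Tanford-derived); hydrophilicity — Hopp & Woods (1981);
# mass — side-chain mass in daltons (PseAAC convention); pK1_alpha_COOH,
# pK2_NH3, pI_25C — standard CRC/Lehninger values at 25 C.
# Each scale is standardized (zero mean, unit population SD over the 20
# residues) before use, so affine rescalings of a column are immaterial.
residue,hydrophobicity,hydrophilicity,mass,pK1_alpha_COOH,pK2_NH3,pI_25C
A,0.62,-0.5,15.0,2.34,9.69,6.00
C,0.29,-1.0,47.0,1.96,10.28,5.07
D,-0.90,3.0,59.0,1.88,9.60,2.77
E,-0.74,3.0,73.0,2.19,9.67,3.22
F,1.19,-2.5,91.0,1.83,9.13,5.48
G,0.48,0.0,1.0,2.34,9.60,5.97
H,-0.40,-0.5,82.0,1.82,9.17,7.59
I,1.38,-1.8,57.0,2.36,9.60,6.02
K,-1.50,3.0,73.0,2.18,8.95,9.74
L,1.06,-1.8,57.0,2.36,9.60,5.98
M,0.64,-1.3,75.0,2.28,9.21,5.74
N,-0.78,0.2,58.0,2.02,8.80,5.41
P,0.12,0.0,42.0,1.99,10.60,6.30
Q,-0.85,0.2,72.0,2.17,9.13,5.65
R,-2.53,3.0,101.0,2.17,9.04,10.76
S,-0.18,0.3,31.0,2.21,9.15,5.68
T,-0.05,-0.4,45.0,2.09,9.10,5.60
V,1.08,-1.5,43.0,2.32,9.62,5.96
W,0.81,-3.4,130.0,2.83,9.39,5.89
Y,0.26,-2.3,107.0,2.20,9.11,5.66
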