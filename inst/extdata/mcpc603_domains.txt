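# Fab domain and CDR annotation in author (PDB) numbering.
# Columns: label chain start end (inclusive). Chains: L = light, H = heavy.
# Domain boundaries use the conventional immunoglobulin-fold split; CDR
# loops: L1 26-37, L2 56-61, L3 97-102, H1 28-32, H2 50-58, H3 102-109.
VL L 1 113
CL L 114 220
VH H 1 122
CH H 123 222
L1 L 26 37
L2 L 56 61
L3 L 97 102
H1 H 28 32
H2 H 50 58
H3 H 102 109
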