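# MKMN two-network case study -- network A (pathological variant).
# Identical to network B except for the additional r3 -> C2 linkage and
# the C2 -> C4 dependency; reconstructed rule set.
input C1
input C3
input C6
input C7
C2 = C1 & r3
C4 = C3 & C2
r1 = C1 & C2
C5 = r1
r4 = C5
r2 = C3 & C4
C8 = r2
r3 = C6 & C7
C9 = r4 | C8 | r3
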