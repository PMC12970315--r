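# MKMN two-network case study -- network B (healthy variant).
# Reconstructed rule set: 13 nodes, 1 OR gate and 3 AND gates.
# Substitute your own rule file to use a different topology.
input C1
input C3
input C6
input C7
C2 = C1
C4 = C3
r1 = C1 & C2
C5 = r1
r4 = C5
r2 = C3 & C4
C8 = r2
r3 = C6 & C7
C9 = r4 | C8 | r3
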