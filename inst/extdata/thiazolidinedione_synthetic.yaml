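# Schematic (synthetic) declaration for a thiazolidinedione-class inhibitor:
# the TZD ring amine donates, its carbonyl oxygens accept, one phenyl ring.
# Atom names are generic, not taken from any deposited model.
res_name: TZD
donors: [N1]
acceptors: [O1, O2, O3]
rings:
  - [T1, T2, T3, T4, T5]
  - [P1, P2, P3, P4, P5, P6]
apolar: [C7, C8]
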