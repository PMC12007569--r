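# Schematic (synthetic) declaration for a triazolopyrimidinone-class
# inhibitor (zaprinast-like): heterocycle donating and accepting hydrogen
# bonds, fused ring treated as one planar system plus a phenyl ring.
# Atom names are generic, not taken from any deposited model.
res_name: TZP
donors: [N2, N6]
acceptors: [O7, N1, N3]
rings:
  - [N1, C2, N3, C3A, C7A]
  - [P1, P2, P3, P4, P5, P6]
apolar: [C9, C10, C11]
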