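# Schematic (synthetic) chemistry declaration for a cyanoacrylate-class
# inhibitor: carboxylate pyruvate-mimic, cyano nitrogen acceptor, furan and
# phenyl rings. Atom names are generic, not taken from any deposited model.
res_name: CYA
acceptors: [O1, O2, N1]
charged_groups:
  carboxylate:
    atoms: [C1, O1, O2]
    sign: -1
rings:
  - [F1, F2, F3, F4, F5]
  - [P1, P2, P3, P4, P5, P6]
apolar: [C2, C3]
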