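# Pyruvate ligand chemistry declaration.
# C1 carboxylate carbon (O1/O2 oxygens), C2 ketone carbon (O3), C3 methyl.
res_name: PYR
acceptors: [O1, O2, O3]
charged_groups:
  carboxylate:
    atoms: [C1, O1, O2]
    sign: -1
apolar: [C3]
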