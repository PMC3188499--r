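# Example configuration for the synthetic toy template written by
# writeFixtures()/`caaxbind.R fixtures`. For a real receptor-peptide
# complex, point the anchors at the equivalent conserved atoms
# (Gln-amide, Arg-guanidinium, and the three thiol-coordination
# side-chain atoms) using chain:resno:atom addresses.
template:
  peptide_chain: P
  ligand_codes: [FAR]
  receptor_chains: [A]
  anchors:
    q_alpha: "A:101:NE2"
    r_beta: "A:102:NH1"
    zn_triad_1: "A:103:SG"
    zn_triad_2: "A:104:OG"
    zn_triad_3: "A:105:OG1"
constraints:
  sd: 0.1
energy:
  weights:
    constraint: 1.0
minimize:
  tolerance: 0.0001
  max_iter: 200
  interface_cutoff: 8.0
classify:
  loose: -0.4
  stringent: -1.1
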