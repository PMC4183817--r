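# I27 pentamer with two 97-residue SAH domains inserted between I27 domains.
# The second SAH cassette brings 3 extra unfolded linker residues
# (back-derived so the predicted contour length is 111 nm).
name: I27_5_SAH_2
detach_rate0: 3.0e-08
detach_distance: 0.4
segments:
- kind: unfolded_polypeptide
  n_residues: 30
- kind: folded_i27
  n_residues: 89
- kind: sah_helix
  n_residues: 97
  delta_g_per_residue: -0.4
  cooperativity_block: 4
- kind: unfolded_polypeptide
  n_residues: 3
- kind: folded_i27
  n_residues: 89
- kind: sah_helix
  n_residues: 97
  delta_g_per_residue: -0.4
  cooperativity_block: 4
- kind: unfolded_polypeptide
  n_residues: 6
- kind: folded_i27
  n_residues: 89
- kind: folded_i27
  n_residues: 89
- kind: folded_i27
  n_residues: 89
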