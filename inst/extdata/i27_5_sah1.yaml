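# I27 pentamer with one 97-residue SAH domain inserted between I27 domains.
# The SAH cassette brings 6 extra unfolded linker residues (back-derived so
# the predicted contour length is 73 nm).
name: I27_5_SAH_1
detach_rate0: 3.0e-08
detach_distance: 0.4
segments:
- kind: unfolded_polypeptide
  n_residues: 30
- kind: folded_i27
  n_residues: 89
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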