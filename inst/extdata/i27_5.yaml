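# I27 pentamer construct (His tag - 5x titin I27 - Cys-Cys anchor).
# Linker/tag residues are pooled into one unfolded segment; the 30-residue
# count is back-derived so the predicted contour length (0.38 nm/residue
# for unfolded residues + 4.5 nm per folded I27) is 34 nm.
name: I27_5
detach_rate0: 3.0e-08
detach_distance: 0.4
segments:
- kind: unfolded_polypeptide
  n_residues: 30
- kind: folded_i27
  n_residues: 89
- kind: folded_i27
  n_residues: 89
- kind: folded_i27
  n_residues: 89
- kind: folded_i27
  n_residues: 89
- kind: folded_i27
  n_residues: 89
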