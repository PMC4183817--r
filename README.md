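# sahspring

Single-molecule force spectroscopy analysis of single α-helix (SAH)
domains, built around the myosin-10 SAH domain inserted into titin I27
polyprotein constructs.

SAH domains are long, isolated α-helices rich in charged residues (Arg,
Lys, Glu) that are stable in solution without tertiary packing. Under
mechanical load they behave unlike both folded domains and Hookean
springs: they lengthen at an approximately **constant low force**
(< 30 pN) without a discrete unfolding peak, so the stored energy grows
linearly — not quadratically — with extension. `sahspring` provides the
models and the complete analysis pipeline needed to study this behaviour
with atomic force microscopy (AFM) pulling data, and a synthetic-trace
generator that reproduces the standard polyprotein experiment for
testing and calibration.

## What is in the package

**Mechanical element models** (`wlc_force`, `wlc_extension`,
`helix_coil_extension`, `plateau_force`, `series_extension`)

- Wormlike chain (WLC) in the interpolation form
  `F = (kBT/p) [ 1/(4(1 − x/l_c)²) − 1/4 + x/l_c ]`
  with persistence length `p` and contour length `l_c`, plus its
  numerical inverse (mutual inverses to 1e-6 relative tolerance).
- A two-state helix–coil element for the SAH domain: blocks of ~one
  helical turn convert between a rigid helical rise (0.15 nm/residue)
  and a coil wormlike chain (0.38 nm/residue contour, p = 0.4 nm) with
  Boltzmann weight `exp[−(ΔG_block − F·Δx_block(F))/kBT]`. The element
  extends along a force plateau near 20 pN — a constant-force spring.

**Pulling simulator** (`simulate_pull`, `simulate_batch`,
`corrupt_trace`, `study_construct`) — constant-velocity pulling of a
cantilever (default 40 pN/nm) in series with a construct; Bell-model
unfolding kinetics `k(F) = k0 exp(F Δx‡ / kBT)` for each folded I27
domain (+28 nm of contour per unfolding), Bell detachment, 5 kHz
sampling, Gaussian force noise, and four deterministic "bad trace"
corruption modes for exercising the selection filter. Shipped constructs:
an I27 pentamer (`i27_5`) and versions with one or two 97-residue SAH
domains inserted (`i27_5_sah1`, `i27_5_sah2`).

**Trace analysis pipeline** (`detect_events`, `select_trace`,
`fit_wlc_segment`, `global_i27_fit`, `peak_to_peak`,
`unfolding_forces`, `align_traces`, `density_map`, `summarize_batch`) —
peak detection, the single-molecule selection filter (five I27
unfoldings followed by exactly one detachment, no unphysical contour
length, global-fit windows Δl_c = 28 ± 1 nm and p = 0.4 ± 0.1 nm),
first-peak and global five-peak WLC fits capped at 100 pN, model-free
unfolding forces and peak-to-peak distances, 100 pN alignment and
1 nm × 2 pN force–extension density maps.

**CD tools** (`to_mre`, `helicity_from_mre222`, `subtract_reference`,
`normalize_melt`, `refolding_fraction`, `melt_cooperativity`,
`synth_spectrum`) — mean residue ellipticity, single-wavelength (222 nm)
helicity estimation, reference subtraction to isolate an inserted helix,
melt normalisation and cooperativity classification, and a
basis-spectrum generator.

**Structure metrics** (`end_to_end`, `drmsd`, `helicity`,
`running_average`, `ideal_helix`, `read_coordsets`) — end-to-end
distance r_NC, superposition-free distance-matrix RMSD, a binary
helicity assignment (O(i)···N(i+4) hydrogen-bond proxy plus φ/ψ basin),
and backbone builders for ideal helices and coils.

## Worked example

Simulate a small batch for the single-SAH construct and run the full
pipeline:

```r
library(sahspring)

con <- study_construct("i27_5_sah1")
batch <- simulate_batch(con, pull_protocol(seed = 20), 15)
summ <- summarize_batch(batch$traces, selection_criteria(), con)
summ
#> <batch_summary> I27_5_SAH_1: 15/15 traces accepted
#>   Fu 169 +/- 18 pN; P2P 23.7 +/- 0.4 nm; lc 76 +/- 0 nm;
#>   p 0.31 +/- 0.01 nm; dlc 28.7 nm; predicted lc 73 nm
```

Every trace shows five I27 unfolding peaks at ~170 pN followed by one
detachment; the SAH domain adds ~39 nm to the first-peak contour length
(76 vs 34 nm for the bare pentamer, against predicted 73 vs 34 nm at
0.38 nm per unfolded residue + 4.5 nm per folded domain) while
producing **no** unfolding peak of its own:

```r
max(sapply(batch$traces,
           function(tr) max_pre_i27_event_force(detect_events(tr))))
#> [1] 0
```

The helix–coil element that produces this signature has a plateau force
of about 20 pN with the default −0.4 kBT/residue helix propensity:

```r
plateau_force(helix_coil_params(97))
#> [1] 20.36215
```

On the CD side, a synthetic 67%-helical spectrum inverts exactly through
the 222 nm single-wavelength estimator:

```r
sp <- synth_spectrum(0.67)
helicity_from_mre222(sp$signal[sp$wavelengths == 222], 98, 10)
#> [1] 0.67
```

`run_reproduction(n_per_construct, seed, out_dir)` chains all of this
for the three constructs and writes a Markdown/CSV report juxtaposing
the recovered statistics with the published reference values
(`afm_reference_stats()`).

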