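---
title: "Models and methods behind sahspring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sahspring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahspring)
```

`sahspring` studies the mechanics of single α-helix (SAH) domains — long,
charge-stabilised helices such as residues 813–909 of myosin-10 — by
combining three ingredients: closed-form mechanical element models, a
stochastic constant-velocity pulling simulator, and the analysis pipeline
used on real AFM polyprotein data. This vignette records the models, the
assumptions, and the numerical and design choices, in enough detail that a
reader can audit or change any of them.

## The mechanical models

### Wormlike chain

Unfolded polypeptide is described by the wormlike chain in the
interpolation form

$$F(x) = \frac{k_BT}{p}\left[\frac{1}{4(1-x/l_c)^2} - \frac14 +
\frac{x}{l_c}\right],$$

with persistence length $p$ and contour length $l_c$. The literature on
polyprotein unfolding names the WLC but rarely its variant; this
interpolation form is the standard choice for polypeptides and is exact in
both the entropic limit ($F \to \tfrac32 k_BT x / (p\,l_c)$) and the
high-force divergence. Temperature defaults to 298 K ("room
temperature"), giving $k_BT = 4.114$ pN nm; both are configurable through
`thermo()`. The inverse $x(F)$ has no closed form and is computed by a
safeguarded Newton iteration on the dimensionless variable $x/l_c$
(convergence tolerance $10^{-12}$; the forward/backward round trip is
accurate to better than $10^{-6}$ relative).

### The helix–coil constant-force element

The SAH domain is represented by a deliberately minimal two-state block
model rather than a full Zimm–Bragg transfer-matrix treatment. Residues
convert in blocks of `cooperativity_block` residues (default 4, about one
helical turn); `n_residues` is split into whole blocks plus one remainder
block. Each block is an independent two-state unit:

- **helix**: a rigid rise of 0.15 nm/residue (canonical α-helix);
- **coil**: a wormlike chain of contour 0.38 nm/residue with
  $p = 0.4$ nm (the same values used for all unfolded polypeptide).

At force $F$ the coil state is favoured by the stretching term
$F\,\Delta x(F)$, where $\Delta x(F)$ is the extension difference between
the coil WLC at $F$ and the helical rise, so the block helix probability
is $1/(1 + e^{(F \Delta x(F) - \Delta G_u)/k_BT})$ with
$\Delta G_u = -m\,\Delta g$ for a block of $m$ residues. Two deliberate
simplifications:

- The stretching energy is taken as $F\,\Delta x(F)$ rather than the
  Gibbs integral $\int_0^F \Delta x\,dF'$. This makes the half-unfolding
  condition exactly $F\,\Delta x(F) = \Delta G_u$, which is what
  `plateau_force()` solves; the difference is immaterial for a
  qualitative plateau element.
- Blocks are independent, so the transition is spread over a few tens of
  pN instead of being a sharp phase boundary, and unfolding does not
  preferentially nucleate at the helix ends (real SAH unfolding does).
  The element still produces the defining behaviour: monotone
  lengthening at low, roughly constant force with no force peak.

One consequence worth knowing: below the force at which the coil WLC
extension first exceeds the helical rise (about 4 pN with the defaults),
tension marginally *stabilises* the helix, so the helix fraction has a
shallow maximum around 3–5 pN before decreasing. The element extension is
nevertheless monotone in force everywhere.

The default helix propensity is $\Delta g = -0.4\,k_BT$/residue, chosen
once so that the plateau force is ~20 pN, inside the < 30 pN band in
which SAH domains are observed to unfold; it lives in the construct
definitions and `helix_coil_params()`, not hard-coded in the mechanics.

## The pulling simulator

`simulate_pull()` advances the piezo by $v\,\Delta t$ per sample
($\Delta t = 1/f_s$; defaults 1000 nm/s and 5 kHz, so 0.2 nm per step)
and solves the force balance $F = k_c\,(z - x(F))$, where $x(F)$ is the
series extension of the construct: one wormlike chain for all
non-helical polypeptide plus one helix–coil element per SAH domain. The
root is bracketed from the previous step's force and solved with Brent's
method to $10^{-9}$; the residual at every accepted step is below
$10^{-6}$ pN.

**Folded domains contribute contour, not a rigid offset.** A still-folded
I27 adds its 4.5 nm folded length to the chain's WLC contour; unfolding
adds `delta_lc_unfold` (default 28 nm) more. This is the standard
polyprotein simulation picture — the trace behaves as a single WLC whose
contour grows stepwise — and it makes the analysis pipeline's global fit
an unbiased estimator of the increment on noise-free data. The
alternative (folded domains as rigid rods in series) introduces a
force-independent offset that a pure WLC fit cannot represent: it pins
the first-peak persistence length at its bound and deflates the fitted
increment by ~1.5 nm. A side effect of the chosen picture is that the
first-peak fitted contour length sits essentially at the predicted value
(34 nm for the bare pentamer); the elevated experimental values
(~47 nm), usually attributed to origin placement and surface effects,
are not emulated.

**Kinetics.** Each still-folded domain unfolds with Bell rate
$k(F) = k_0 e^{F \Delta x^\ddagger / k_BT}$; tip/surface detachment is an
analogous process. Within a time step all processes compete as risks and
at most one fires (an unfolding collapses the force, so the probability
of a second barrier crossing in the same 0.2 ms is negligible; sampling
them independently instead produces artificial same-step double events).
The commonly cited literature values for I27's kinetics are
$k_0 = 3.3\times10^{-4}$ s$^{-1}$ and
$\Delta x^\ddagger = 0.25$ nm; holding $k_0$ fixed, the shipped
calibration (`default_i27_bell()`, derived in `scripts/tune_bell.R`)
sets $\Delta x^\ddagger = 0.33$ nm so that the *pipeline-measured* mean
unfolding force at the default protocol is ~174 pN. Detachment defaults
($3\times10^{-8}$ s$^{-1}$, 0.4 nm) put detachment at ~250 pN after the
last unfolding while making earlier detachment negligibly rare.

**Noise.** White Gaussian noise of 6 pN standard deviation is added to
the reported force only — an approximation to filtered cantilever thermal
noise. The extension channel is the noise-free molecular extension, and
neither 1/f drift nor nonspecific adhesion at short extensions is
simulated by default; the `drift` corruption mode adds a strong linear
baseline when a bad-trace fixture is needed. The I27 unfolding
intermediate (the "hump" near 100–120 pN) is not simulated; the
pipeline's 100 pN fit cap is honoured regardless, so fits never enter the
regime where the hump would matter.

**Constructs.** The three shipped constructs are an I27 pentamer and
versions with one or two 97-residue SAH domains inserted between I27
domains. Linker and tag residue counts are not published; the fixtures
use 30 unfolded residues for the bare pentamer and 6 and 3 additional
linker residues with the first and second SAH cassette, back-derived so
the predicted contour lengths (0.38 nm per unfolded residue + 4.5 nm per
folded domain) come out at 34, 73 and 111 nm. The YAML fixtures state
this openly.

## The analysis pipeline

**Peak detection** operates on a 5-sample running mean of the force. A
candidate local maximum above 50 pN becomes an event if the smoothed
force falls by at least 30 pN within 50 samples; candidates without a
qualifying valley between them are merged (the higher wins). Peak
positions and forces are then re-read from the raw signal within one
smoothing window of the smoothed apex, because smoothing both shifts and
lowers a sharp sawtooth apex. An event is classified as the detachment
when the force reaches baseline (3 estimated noise SD of zero) within the
drop window and stays there for most of the following 250 samples; a
shorter window misclassifies the low-force region after an early I27
unfolding, when the relaxed chain reloads slowly from a few pN. The
noise SD is estimated robustly from first differences
(`mad(diff(F))/sqrt(2)`), so detection is self-contained per trace.

**Selection** applies, in order: exactly five unfolding events; exactly
one detachment; apparent contour length at the detachment peak no more
than 40 nm beyond the fully unfolded construct length (origin-placement
allowance); then global-fit windows $\Delta l_c = 28 \pm 1$ nm and
$p = 0.4 \pm 0.1$ nm. The first failing rule is named in the rejection
reason, and verdicts are deterministic. The four corruption modes of
`corrupt_trace()` are each caught by the rule built to catch them.

**WLC fitting** uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with
starting values $l_c = 1.2\times$ the largest fitted extension and
$p = 0.4$ nm, bounds $l_c \in (x_{max}, 500]$ nm and
$p \in [0.05, 2]$ nm. The first-peak fit uses points between 5 and
100 pN of the rising edge to the first unfolding peak. The global fit
shares one $p$ across the five rising edges and constrains their contour
lengths to $l_{c,1} + k\,\Delta l_c$; it uses points between 10 and
100 pN. The lower bound matters: fitting only a narrow high-force window
(say 50–100 pN) leaves the problem on the long, curved $(p, l_c)$ ridge
where 6 pN force noise biases the shared persistence length downward by
~0.09 nm and inflates the increment by ~1 nm, while including the
10–50 pN shape removes almost all of that bias (recovery 28.2 nm and
0.38 nm on the default batch). On noise-free traces the global fit is
exact to four decimals.

**Model-free statistics.** Unfolding forces are the raw peak forces of
unfold events. Peak-to-peak distances follow the lower-peak rule: the
reference force is the smaller of the two adjacent smoothed peak heights
and the distance is measured between the linear-interpolated crossings
of that force on the two rising edges. Alignment shifts each trace so
its last upward 100 pN crossing before the detachment peak sits at a
common reference, and `density_map()` bins aligned points on a half-open
1 nm × 2 pN grid.

## CD computations

Mean residue ellipticity is $\theta_{mdeg}/(10\,c\,N\,l)$ with molar
concentration $c$, residue count $N$ and path length $l$ in cm. Helicity
uses the single-wavelength 222 nm method with endpoints
$[\theta]_H = -40000(1 - 2.5/N) + 100T$ and $[\theta]_C = 640 - 45T$
($T$ in °C). The exact constants behind the published 67% figure are not
reproduced in the source text; these are the common values for this
method, recorded here as an assumption — estimates at the 1–2% level
depend on that choice. Reference subtraction (to isolate an inserted SAH
from a composite construct) is pointwise in millidegrees, refuses
mismatched wavelength grids, and requires molar concentrations equal
within 5%. Melt cooperativity is classified by comparing a two-state
logistic against a straight line via BIC: cooperative requires the
sigmoid to win by more than 10 *and* a 10–90% transition width under
20 °C, so both gradual SAH-like melts and pure noise fall on the
non-cooperative side.

The synthetic spectrum generator mixes helix/sheet/coil basis curves
shipped as `inst/extdata/cd_basis_synthetic.csv`. These are smooth
Gaussian-band constructions with the canonical features (helix double
minima at 208/222 nm, sheet minimum near 217 nm, coil minimum near
198 nm) — *not* digitised reference spectra — and are anchored at 222 nm
to the helicity estimator's endpoints, so the generator–estimator round
trip is exact at zero noise. Tests passing on these spectra validate the
arithmetic and the anchoring, not the spectroscopy of real proteins.

## Structure metrics

`end_to_end()` is the N-terminal nitrogen to C-terminal carbonyl carbon
distance; `drmsd()` is the RMS deviation over all unique backbone atom
pairs of the internal distance matrices, superposition-free by
construction. The helicity assignment is a binary proxy, not a DSSP
reimplementation: a residue is helical when its carbonyl oxygen is
within 0.35 nm of the backbone nitrogen four residues downstream and its
φ/ψ angles fall in the α basin (φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]).
On generator-built ideal helices it scores 1.0 and on extended or random
chains ≤ 0.1, but it will differ from continuous DSSP-style assignments
by a few percent on real structures. The backbone builder places N, CA,
C, O atoms by natural-extension (NeRF) steps from standard bond lengths
and angles with ω = 180°; the ideal helix uses φ = −57°, ψ = −47°,
giving a rise of ~0.157 nm/residue and an O(i)···N(i+4) distance of
0.31 nm.

## What the synthetic data do and do not show

The generator emulates the sawtooth phenomenology of polyprotein
pulling: WLC loading, stochastic Bell unfolding with the correct
loading-rate dependence, a low-force SAH plateau without a peak,
detachment, sampling and force noise, and four realistic failure modes.
It does not emulate nonspecific adhesion, baseline drift (outside the
corruption mode), unfolding intermediates, refolding during approach, or
the origin-placement scatter that widens experimental contour-length
histograms. Recovery results on these traces therefore demonstrate that
the pipeline measures what the models put in — an estimator-consistency
statement — and that the SAH element reproduces the qualitative
signatures; they are not a substitute for analysing real traces.

Problem sizes used by the shipped tests and the acceptance script — 50
traces per construct for the recovery batches, smaller cached batches
for unit tests — were chosen as the package's own compromise between
Monte Carlo error (standard error of the mean increment ~0.015 nm at
n = 50) and turnaround time.

## Known limitations

- The helix–coil element is equilibrium-only: it reverses on unloading
  with no hysteresis, so refolding kinetics cannot be studied with it.
- The independent-block model has no end-nucleation preference and a
  softer transition than a cooperative helix–coil theory would give.
- The detachment contour-length rule fits the final rising edge with a
  free persistence length; on very short final edges it falls back to
  the peak extension, which is conservative.
- `melt_cooperativity()` assumes a single transition; multi-phase melts
  will be classified by whichever branch fits better.
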