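---
title: "Methods: models, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrbridge)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, the design of the synthetic-data generators,
and the numerical choices that were genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Skeletons and resampling

Neuron tracings are rooted trees of 3D nodes; all coordinates are held in
nanometres as doubles (SWC files are read as micrometres by default and
scaled ×1000). Unbranched dendrite analyses work on the root-to-tip
polyline.

Resampling fits one natural cubic spline per coordinate against the
cumulative chord length of the input polyline and then places nodes at
equal arc-length steps (default 320 nm, the interval the traceable-length
profile is defined on). Choices worth recording:

- **Parameterisation**: cumulative chord length. Arc-length
  re-parameterisation is recovered afterwards by numerical integration,
  so the chord/arc distinction only affects the (tiny) spline fitting
  error, not the output spacing.
- **Boundary conditions**: natural (zero second derivative). Nothing in
  the procedure depends on endpoint curvature, and natural splines avoid
  inventing curvature beyond the traced tips.
- **Arc-length integration**: the spline is sampled on a per-interval
  refined grid, doubling the subdivision (8 → 64 per input interval)
  until the total length changes by < 1e-9 relative; equal-arc positions
  are then found by monotone interpolation of the cumulative length.
- **The final point is always emitted**, even when the last step is
  shorter than the spacing — a dendrite tip must never be truncated.
- **Degenerate inputs**: paths with ≤ 3 distinct points fall back to
  piecewise-linear interpolation (a cubic is under-determined); repeated
  points are collapsed; a single distinct point is an error.

## Traceable length

The distance profile records, for every resampled test node, the distance
to the *nearest* resampled reference node. Distances are node-to-node,
not node-to-segment: at 320 nm spacing the segment-projection correction
is bounded by half a step and is negligible against thresholds of 6–12 µm.
A tracing is lost at the *first* sample above the threshold (no
debouncing; a `min_run` option exists but defaults to 1, matching the
literal definition). The profile starts at the shared soma seed (arc 0),
soma included.

Thresholds are parameters of `eval_params()`: 12 µm lost / 35 µm linked
for the olfactory-bulb setting, 6 µm lost for the hippocampal one. The
package deliberately does not pick thresholds from the bimodal distance
histogram automatically; the histogram can be exported for inspection but
threshold choice is the analyst's.

Cohort summaries report per-tracer means, the cross-tracer mean ± SEM,
and pooled Tukey box statistics (whiskers at the most extreme points
within 1.5 × IQR of the quartiles). Consensus selection among tracings
flagged correct takes the longest tree by cable length, first-in-order on
ties; correctness flags are inputs, since in the original workflow they
come from manual curation.

## Landmark transforms and the dataset graph

Scale-offset and affine transforms are closed-form least squares. The
thin-plate spline uses the 3D biharmonic kernel *U(r) = r* — not the 2D
*r² log r* — because all spaces here are volumes. At zero regularisation
it interpolates its landmarks exactly (residuals at machine precision,
asserted < 1 nm in tests); positive regularisation adds to the kernel
diagonal.

TPS transforms have no closed-form inverse. The registered inverse edge
is a TPS fitted to the swapped landmark pairs, documented as approximate;
round-trip error on interior points is measured in the tests at well
under 0.5% of the bounding-box diagonal. Affine and scale-offset edges
invert exactly.

The dataset graph routes by **fewest edges**, with ties broken
lexicographically by space name so composition is deterministic. Residual
quality does not influence routing — mirroring how such graphs are used
in practice, where the analyst controls which edges exist.

Landmark files are JSON with explicit space names and a fixed `nm` unit
field, because the common CSV exports of interactive warping tools are
pair-specific and unit-ambiguous.

## Fourier Shell Correlation

Shells are one frequency-voxel wide, binned by **rounded** radius (the
community default; the floor convention differs only in shell population
at the boundaries and can matter for very small volumes). Frequencies are
normalised per axis before radius binning, so non-cubic volumes are
handled. Shell 0 holds only DC; analysis starts at shell 1.

Criterion curves as functions of the shell voxel count *n*:
1-bit `(0.5 + 2.4142/√n)/(1.5 + 1.4142/√n)`, ½-bit
`(0.2071 + 1.9102/√n)/(1.2071 + 0.9102/√n)`, 3σ `3/(√(n/2) + 1)` (the
`+1` variant is the default; the bare `3/√(n/2)` is available behind a
flag, since the two families coexist in the criterion literature), and
the constant 1/7. The resolution is the first shell whose FSC falls below
its threshold, refined by linear interpolation of FSC-minus-threshold
between adjacent shells; a curve that never crosses within Nyquist
returns a `beyond_nyquist` flag rather than a number.

The high-frequency normalisation assumes correlations in
[1/3, 1/2] cycles/voxel are truly null, estimates the band mean *m* of
the averaged curve, and rescales every curve as `(fsc − m)/(1 − m)` — an
affine map fixing FSC = 1 and sending the band mean to 0. A subtract-only
mode exists; the rescale is the default because it preserves the FSC = 1
anchor that the criterion formulas assume.

EM split-halves are built from odd/even slices with 2×2 in-plane mean
pooling (voxel size doubles, isotropic again when the slice pitch is
twice the pixel). Tomographic split-halves (odd/even projection angles)
are accepted as pre-made half volumes; reconstructing them belongs to the
tomography module.

## Spine statistics

Densities pool counts over all branchlets of the same dendrite type per
cell and divide by pooled shaft length. A branched spine is a single
annotation row and therefore counts once — including in spine-apparatus
counts when both heads carry a cistern.

The soma-layer line is fitted by total least squares (first principal
axis) rather than y-on-x regression: depth is a Euclidean perpendicular
distance, and TLS makes it invariant to the image axes. A y-on-x mode is
kept for strict replication. The deep side must be given explicitly as a
hint vector; no algorithmic rule can orient the layer from coordinates
alone.

Inter-spine gaps are successive differences of sorted attachment
positions within a branchlet, never across branchlets; branchlets with
fewer than two spines are excluded. Under a homogeneous Poisson process
gaps follow `f(x) = λe^{−λx}` with λ a *rate* (the MLE is the reciprocal
mean gap). Inter-apparatus gaps are by default tested against the
all-spines fitted exponential, not a refit (a refit option exists).

The one-sample KS test with an estimated rate is mis-calibrated if the
fitted CDF is treated as fixed; the classical plug-in p-value is
conservative. Both routes are provided: `naive` (the standard KS
distribution, for replicating the published protocol) and
`parametric_bootstrap` (default; B = 999 exponential resamples, rate
refitted on each, p = (1 + #{D\* ≥ D})/(B + 1)). The acceptance suite
verifies the bootstrap's type-I error at α = 0.05 lies in the exact
binomial 99% interval over 1000 null replicates.

Density-versus-depth uses ordinary least squares with the two-sided
t-test on the slope (n − 2 df) and the pointwise 95% confidence band of
the mean response, symmetric about the fitted line.

## Tomography core

Normalisation is the elementwise `(p − d)/(f − d)`, failing loudly (with
the pixel index) wherever `f − d ≤ 0`. The Paganin filter is written in
the δ/β-ratio parameterisation, `H(u,v) = 1/(1 + πλz(δ/β)(u² + v²))`,
defaults 22 keV / 52 mm / 325 nm / δ/β = 1; absolute δ and β may be
supplied instead (e.g. δ = 2e−6, β = 6e−7, ratio 10/3). The filter's DC
gain is exactly 1 and every other frequency is strictly attenuated; both
the filtered intensity and the `−log` thickness map are exposed, since
pipelines differ on where the log is taken. Non-positive values before
the log are clipped at a floor with the clip count reported.

Back-projection zero-pads each row to √2 × width (edge replication
behind a flag), applies the Ram-Lak ramp built in *real* space
(h(0) = 1/4, h(odd k) = −1/(πk)², h(even) = 0) — the real-space
construction avoids the DC bias (cupping) of a naive `|f|` multiplication
— and accumulates bilinear back-projections scaled by π/n_angles. Only 2D
parallel-beam slices are implemented (the geometry is slice-separable);
ring removal and centre-finding are deliberate pass-through stubs.

## Synthetic-data generators

The generators define the package's working conditions; their defaults
are fixed once and shared by tests and the acceptance script.

**Dendrite cohorts.** Truth dendrites are persistent random walks,
200 µm long with angular diffusion low enough to stay nearly straight —
the geometry of mitral-cell apical dendrites crossing the external
plexiform layer. Tracer copies get *smooth* low-frequency jitter
(RMS 500 nm, correlation length ~20 µm): white per-node jitter would
inflate path length by several percent at realistic amplitudes, which no
human tracing does, whereas smooth jitter changes length by < 0.1%.
Linkage failures (probability q) place a sustained perpendicular
wrong-turn at an arc position uniform in [0, 20 µm]: with a 12 µm lost
threshold the resulting loss positions land in roughly [12, 32] µm —
inside the ~40 µm linkage region and below the 35 µm link threshold, so
the lost-at-linkage fraction equals q by design. (Departure points drawn
across the full 40 µm window would push part of the failures past the
35 µm classification boundary; geometry forces the first exceedance at
least one lost-threshold beyond the departure, so the window is kept
short of the boundary by that margin.) Late departures (probability q2
among the rest) are uniform beyond the window. The true per-tracer error
process in real data is of course unknown; this q/q2/σ model is a stated
assumption, not a claim about any dataset.

**FSC pairs.** A shared band-limited Gaussian field (hard spherical
cutoff) plus independent white noise per half. In-band Fourier
coefficients of the signal carry unit white power, so noise of standard
deviation 1/√snr yields per-shell SNR exactly `snr` below the cutoff and
the closed-form expectation FSC = snr/(snr + 1); above the cutoff the
expectation is 0 with standard deviation ~1/√n.

**Spiny cells.** Somata on a known layer line with designed signed
depths; spine positions are homogeneous Poisson (default λ = 1.5/µm over
~2 mm of total shaft across 7 cells, matching the scale of a realistic
CA1 annotation campaign of ~3000 spines); spine-apparatus flags are
Bernoulli with p(depth) = p₀ + β·depth (defaults p₀ = 0.14, β = 0.002/µm
over ±20 µm, keeping p inside [0.10, 0.18]). The expected
apparatus-density slope against depth is λβ, which the coverage test
recovers inside its own 95% CI in ≥ 90% of replicates.

**Landmark deformations.** Targets are a known affine plus a smooth
random sinusoidal displacement with at most half a period across the
domain — gentle mesoscale distortion of the kind embedding and shrinkage
produce. At 60 landmarks a TPS recovers held-out displacements to a few
percent of the amplitude; substantially higher-frequency fields are not
recoverable at that landmark density and are not what landmark warping is
used for.

**Phantoms.** Deterministic discs and ellipse nests with known support
masks, plus seeded Gaussian blobs.

All generators draw from independent substreams derived from one master
seed (seed × prime + label hash, mod 2³¹), so one module's tests never
perturb another's draws; identical configuration is bit-reproducible.

## What the synthetic tests do and do not show

Passing tests demonstrate that the procedures are implemented correctly
(against closed forms, brute-force oracles and designed generators) and
are well-calibrated at the stated conditions. They do not validate the
biological assumptions on real data: real tracer errors are not a two-mode
departure process, real spine processes need not be homogeneous Poisson,
real deformation fields are not band-limited sinusoids, and real
reconstruction noise is structured (rings, beam hardening) in ways the
generators deliberately omit.

## Problem sizes

Default suite sizes: 64³ voxel FSC volumes (500-voxel ROI cubes, 100 for
the low-resolution modality, remain the recommended configuration for
real data and are config defaults only), 200-dendrite single-tracer
cohorts, 1000 KS null replicates at B = 199 with 200 gaps, 500
depth-regression replicates at n = 7 cells, 128-pixel phantoms at up to
720 angles. These sizes give the statistical resolution the calibration
checks need while keeping the whole suite comfortably desk-scale.
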