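# corrbridge

Quantitative analysis of correlative multimodal microscopy experiments in
which the same block of brain tissue is imaged by in vivo 2-photon
microscopy, synchrotron X-ray tomography with propagation-based phase
contrast (SXRT), laboratory micro-CT (LXRT) and serial block-face electron
microscopy (SBEM). The package is aimed at people running or evaluating such
pipelines: it covers moving annotations between dataset coordinate systems,
scoring how far neurites can be traced in the lower-resolution modality
against EM ground truth, estimating image resolution from split-half
volumes, analysing dendritic-spine spatial statistics against a Poisson
null, and a minimal phase-retrieval + reconstruction core — all exercisable
end-to-end on seeded synthetic data, with no imaging downloads.

## What it computes

**Traceable length.** A test tracing (e.g. an apical dendrite followed in
SXRT) and a reference tracing (the EM consensus, warped into the same
space) are both resampled every 320 nm along a chord-length cubic spline.
For each test node the Euclidean distance to the nearest reference node is
recorded as a function of arc position; the tracing is *lost* at the first
position where this distance exceeds a threshold *d*\* (12 µm for
olfactory-bulb dendrites, 6 µm for hippocampal ones), and the traceable
length is that arc position (or the full length if never exceeded).
Tracings are classified `linked_kept` / `linked_lost` / `lost_at_linkage`
/ `too_short` around a 35 µm linkage threshold, and cohorts are summarised
as per-tracer means, cross-tracer mean ± SEM and Tukey box statistics.

**Warping.** Landmark pairs between named dataset spaces fit scale-offset,
affine, or 3D thin-plate-spline transforms (biharmonic kernel
*U(r) = r*, affine part, exact interpolation at zero regularisation).
Transforms are edges of a dataset graph; `compose_path()` routes any
space to any connected space, and `warp_skeleton()` moves whole tracings.

**Resolution (FSC).** For two half-volumes sharing signal but with
independent noise, the Fourier Shell Correlation per frequency shell *r*
is FSC(r) = Re Σ F₁F₂\* / √(Σ|F₁|² Σ|F₂|²). Resolution is read at the
first crossing below a criterion curve: 1-bit, ½-bit, 3σ, or the fixed
1/7 line. A high-frequency normalisation removes artifactual correlation
floors introduced by shared reconstruction filtering.

**Spine statistics.** Spine densities per cell and dendrite type
(counts / pooled shaft length), signed soma depth from a total-least-squares
pyramidal-layer line, inter-spine gap distributions tested against the
exponential law *f(x) = λe^{−λx}* implied by a homogeneous Poisson
process (one-sample KS, with a parametric-bootstrap calibration for the
estimated rate), and OLS regression of spine-apparatus density on soma
depth with its 95% confidence band.

**Tomography core.** Flat/dark normalisation (p−d)/(f−d), Paganin
single-distance phase retrieval (filter 1/(1 + πλz(δ/β)(u²+v²)),
δ/β = 1 at 22 keV, 52 mm, 325 nm by default), parallel-beam forward
projection, and Ram-Lak filtered back-projection with √2 outer padding.

## Worked example

```r
library(corrbridge)

# a synthetic tracing cohort: 20 dendrites, 3 tracers, 25% linkage failures
coh <- gen_dendrite_cohort(n_cells = 20, q = 0.25, n_tracers = 3, seed = 42)
truth_names <- vapply(coh$truth, function(t) t$name, character(1))
res <- dplyr::bind_rows(lapply(seq_len(nrow(coh$traces)), function(i) {
  evaluate_tracing(coh$traces$tree[[i]],
                   coh$truth[[match(coh$traces$cell_id[i], truth_names)]],
                   cell_id = coh$traces$cell_id[i],
                   tracer_id = coh$traces$tracer_id[i])
}))
cohort_summary(res, exclude_statuses = "lost_at_linkage")
#> <cohort_summary> n = 45
#>   traceable length: 195.7 +/- 3.5 um (cross-tracer mean +/- SEM)
#>   pooled median [Q1, Q3]: 202.0 [201.7, 203.0] um
#>   status counts: linked_kept 42, linked_lost 3, lost_at_linkage 15
```

Excluding the tracings lost at the soma-dendrite linkage region leaves the
cross-tracer expected traceable length at the full designed dendrite length
(200 µm), with a small SEM — the same qualitative behaviour the procedure
is designed to expose on real cohorts.

```r
# split-half resolution of a synthetic 325 nm-voxel volume, SNR 4 in band
pair  <- gen_fsc_pair(shape = 64, cutoff = 0.25, snr = 4,
                      voxel_size = 325, seed = 7)
curve <- compute_fsc(pair)
resolution_from_curve(curve, "half_bit")
#> # A tibble: 1 × 4
#>   criterion crossing_freq resolution_nm beyond_nyquist
#> 1 half_bit          0.262         1241. FALSE
```

The ½-bit crossing sits one shell above the generator's 0.25 cycles/voxel
band limit, i.e. the estimate recovers the designed resolution
(325 nm / 0.26 ≈ 1.2 µm). `autoplot(curve)` overlays the criterion curves.

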