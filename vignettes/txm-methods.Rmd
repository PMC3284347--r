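---
title: "Models and methods behind txmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind txmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmkit)
```

`txmkit` evaluates full-field transmission X-ray microscopy (TXM) data:
mosaic stitching, dual-energy elemental mapping, tomographic
reconstruction, and per-pixel XANES spectro-imaging. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices, and — importantly — what the synthetic
phantoms do and do not establish.

## Working in optical density

Every analysis stage operates on optical density, `OD = −ln T`, where the
transmission `T` is the sample image divided by a reference (flat-field)
image recorded without the sample at the same energy. OD is additive in
absorber thickness (Beer–Lambert), which is what makes the XANES edge jump
proportional to the areal concentration of the edge element and makes 2E
difference maps quantitative. Whether to subtract transmission or OD is
genuinely open in the tool lineage this package follows; OD was chosen and
is used consistently.

Two floors keep the conversion total: transmission below `1e-6` is clipped
(`−ln` would otherwise produce `Inf`; the clip count is reported), and
reference pixels below `1e-6 ×` the reference median are flagged invalid
rather than silently propagated.

## Zone-plate optics and magnification

A Fresnel zone plate of diameter `D` and outermost zone width `Δ` has
first-order focal length `f = DΔ/λ`, linear in photon energy since
`λ = hc/E` (`hc = 1239.842 eV·nm`). With the sample-to-detector distance
`L` fixed, the thin-lens closure `1/u + 1/v = 1/f`, `u + v = L` has the
magnifying root `u = (L − √(L² − 4fL))/2`, so magnification
`M = v/u` *decreases* with energy and a real focus requires `f < L/4`.
Images recorded at different energies are therefore rescaled about their
center by `s = M_ref/M` (bicubic Catmull-Rom, edge replication) before any
pixel arithmetic; `s` outside `[0.5, 2]` is rejected as absurd metadata.
All of this is driven by metadata — the package never estimates scale from
image content unless the optional log-polar stage is invoked explicitly.

## Phase correlation

Translation between frames is measured from the whitened cross-power
spectrum: `R = F_ref·conj(F_mov) / |F_ref·conj(F_mov)|` (with a floor of
`1e-12 × max|cross spectrum|` against division blow-up), whose inverse
transform is an impulse at the displacement. Conventions that the rest of
the package relies on:

* the returned `(dy, dx)` is what is *added to the moving image's
  coordinates* to land on the reference; `translate_image(moving, dy, dx)`
  aligns it.
* a Hann window is applied by default (stacks are not periodic); for
  genuinely circular data it can be disabled, in which case integer shifts
  are recovered exactly (the correlation surface is an exact discrete
  delta, and the parabolic refinement returns offset 0 there).
* sub-pixel refinement is a separable 3-point parabolic fit, clamped to
  ±0.5 px — adequate for the ≤0.5 px accuracy the pipelines need and free
  of Fourier-upsampling machinery.
* `peak_quality` is the normalized correlation peak in `[0, 1]`; frames
  below `q_min = 0.05` are *flagged, never dropped* — the caller decides.

Rotation/scale registration by log-polar resampling of the spectral
magnitudes exists as an optional second stage (`phase_correlate_rotscale`),
off by default: translation is the primary physical error mode of the
instrument.

## Mosaic stitching

Motor positions seed the layout (`(motor − min motor)·1000 / pixel_size`),
so stitching starts from encoded coordinates instead of blind search. For
every 4-neighbour pair whose nominal overlap is a strip of at least 16 px,
phase correlation over the cropped overlap measures the residual error, and
all tile positions are solved jointly by least squares with tile 1 anchored
(links below `q_min` are dropped; disconnected components fall back to
nominal with a warning). A global least-squares solve distributes
inconsistent link errors instead of accumulating them along a greedy chain.
Note the anchor makes positions identifiable only up to a global
translation — truth comparisons must remove the mean offset.

Blending uses a separable feathering weight per tile: a linear ramp from
`~0` at the border to 1 at the feather width (the measured overlap extent,
floor 8 px), with the half-pixel offset `w = (d + 0.5)/fw` so that a lone
tile's weights cancel exactly and single-tile regions are reproduced
bit-for-bit. The output is `Σwᵢtileᵢ/Σwᵢ` — a convex combination, so no
overshoot is possible, and the low-weight corners (poorest signal-to-noise)
contribute least.

## Tomography

Parallel-beam geometry throughout: the TXM objective forms an image, so
projections are effectively parallel at these fields of view. The forward
projector (rotation by bilinear resampling, column sums) is both the test
oracle and the measurement model of the ART system matrix — the two share
one geometry helper, so algebraic reconstruction inverts exactly the
operator the phantoms apply.

**FBP.** Projections are ramp-filtered in the frequency domain
(zero-padded to ≥2× the detector width at the next power of two; Ram-Lak,
Shepp-Logan or Hann apodization) and back-projected with linear
interpolation. The integration weight is `Δθ` radians per view — `π/n`
for a 180° span and half that for 360° scans, where every line orientation
is sampled twice. (A π/(2n) variant was considered and rejected: on a
unit-density disk it reconstructs 0.5 instead of 1.0.) A region of
interest restricts back projection to a sub-grid and is bit-consistent
with cropping the full reconstruction.

**ART.** Kaczmarz row action in deterministic angle-major order,
`x ← x + relax·(pᵢ − ⟨aᵢ,x⟩)/‖aᵢ‖²·aᵢ`, optional non-negativity clamp per
sweep, defaults `relax = 0.25`, 10 sweeps; a divergence guard stops after
three consecutive sweeps of growing residual. Deterministic ordering keeps
output bit-reproducible; it also converges more slowly on pathological
inputs (an isolated impulse needs ~30 sweeps at `relax = 1` to reach a 5%
residual), which is the accepted cost. ART's practical advantage is
sparse-view data: at 45 views of a 64² phantom it beats FBP by ~3× in
RMSE.

**Jitter correction.** Stage jitter displaces each projection randomly and
must be separated from genuine parallax (features really do move as the
sample rotates). The auto mode chains phase correlation between
consecutive angles and accumulates; the accumulated trend attributable to
parallax is removed with a *harmonic* model `a + b·sinθ + c·cosθ` — the
exact law for the projected position of any rigid feature in parallel
beam — rather than the low-order polynomial one might first reach for (a
quadratic cannot follow a sinusoid across 180° and leaves ~2 px of
parallax in the "jitter"). Because chained correlation accumulates
random-walk error, a center-of-mass consistency refinement follows: the
projected intensity centroid must itself obey the harmonic law, so its
residual is residual jitter. The refinement is iterated to a fixed point
(≤4 rounds) because large initial errors interact nonlinearly with edge
handling. Two caveats are inherent and documented: jitter components that
happen to lie in the harmonic span are unidentifiable by *any*
consistency argument and are absorbed into the trend; and the
center-of-mass step assumes the specimen stays fully inside the field of
view. A template-tracking mode (normalized cross-correlation of a
user-chosen feature box) covers cases where it does not.

**Rotation center.** For ~180° scans the last projection must mirror the
first about the rotation axis; the center minimizing the mirror mismatch
is searched on a 0.25 px grid (±12.5% of the width). For ~360° scans the
0°/180° pair is used. Any other span returns the geometric center with a
warning.

## XANES imaging

The analysis chain mirrors established practice for absorption-edge
spectro-imaging:

1. **Edge jump** `J = ⟨OD⟩post − ⟨OD⟩pre` over user-defined windows;
   proportional to areal concentration.
2. **Noise filter**: keep pixels with `J ≥ k·σ_pre`, where `σ_pre` is the
   pixel's own pre-edge *sample* standard deviation (its XANES noise
   level) and `k` (default 3) is the user factor. The mask is monotone in
   `k`. A corner case worth knowing: on strictly noiseless synthetic data
   `σ_pre ≈ 0` and the threshold cannot reject empty pixels — real data
   always carries noise.
3. **Normalization**: ordinary least-squares lines through the pre- and
   post-edge windows, `μn = (μ − L_pre)/(L_post − L_pre)`; pixels whose
   baseline slopes fall outside `[slope_min, slope_max]` (defaults: pre
   ≤ 0.01, post ≤ 0.02 OD/eV — the tool lineage gives no numbers, these
   are user-overridable) or whose edge step at `E0` is non-positive are
   masked and zeroed at all energies.
4. **Edge energy**: the energy where the normalized spectrum first crosses
   0.5 upward, linearly interpolated, scanned strictly between the
   windows; more noise-robust than a derivative and robust to post-edge
   oscillations by taking the *first* crossing. `NaN` where no crossing
   exists. The estimate carries a small bias when the true profile has
   curved tails inside the fit windows (the linear baselines chase them);
   for an arctangent of width 1.5 eV under the default windows it is
   ≈0.04 eV — well under typical scan steps.
5. **Clustering**: a histogram of edge energies on bins aligned to the
   scan grid (bin width = energy step, the experimental precision);
   selected bins become labeled clusters with mean member spectra.
6. **LC fitting**: per-pixel non-negative least squares against normalized
   reference spectra on `[pre_hi, post_hi]`. Weights are *not* constrained
   to sum to one — amplitude is absorbed by the edge-jump weighting in the
   phase map, and an unconstrained option exists. NNLS is solved exactly
   by support enumeration (all 2ᵏ−1 supports for k ≤ 8 references,
   vectorized across pixels; the optimum must be the best feasible
   support). Fit quality is the R-factor `Σ(μ−fit)²/Σμ²`: zero iff exact,
   invariant under common positive rescaling.
7. **Edge-jump vs R-factor plane**: pixels with high concentration but
   poor fit betray a phase missing from the reference set; rectangles or
   polygons in `(J, R)` space become clusters.
8. **RGB phase maps**: channel fractions from the weights (surplus
   references summed into a designated channel), normalized by `Σw`, then
   multiplied by the edge jump scaled to `[0, 1]` at its 99th percentile
   (robust to hot pixels). Weak — hence noisy — pixels fade to black,
   which is why no additional R-factor filter is needed.

## The synthetic world

The phantoms are pure functions of their parameters and a seed, and return
ground truth alongside the data. Their defaults are a deliberate "stated
world", chosen once for physical plausibility:

* **XANES stack**: 128×128 px, 50 energies over 7080–7200 eV (an Fe-K-like
  scan; pre 7080–7110, post 7150–7200, E0 7125); three phases with
  arctangent edges at 7116/7123/7130 eV (width 2 eV — oxidation-state
  scale shifts) distinguished also by white-line amplitudes
  (0.35/0.15/0), because real references differ in shape, not only edge
  position; two pure disks, one pure disk, and a block mixing phases 1–2
  along a gradient; a smooth thickness dome (0.9–1.4); per-pixel linear
  baselines with slopes up to 0.002 OD/eV *carried by the specimen*
  (scattering scales with thickness — an empty beam path cannot have a
  material slope) plus ±2×10⁻⁴ OD/eV detector drift; Gaussian OD noise
  σ = 0.05. Reference spectra are the normalized noiseless pure-phase
  spectra; the truth edge-energy map comes from the noiseless stack run
  through the same normalization, so recovery tests measure the effect of
  noise, not of the estimator's (known, small) bias.
* **Mosaic tiles**: cut from a master with the requested overlap; *true*
  positions jittered by integers in ±jitter while the motor metadata
  encodes the nominal grid; optional radial vignetting (the corner
  signal-to-noise deficit that motivates feathering) and Gaussian noise.
* **Projection series**: forward projections of a 2D phantom extruded with
  a smooth slice profile that fades to ~0 at the top and bottom rows
  (empty space surrounds a real specimen; this also keeps translation
  edge-effects out of the center-of-mass law), degraded by per-angle
  uniform jitter and Gaussian noise.

What a green test establishes — and what it does not: the phantoms share
the package's own interpolation and projection operators (an
"inverse-crime" setup), so recovery results certify the algorithms'
internal consistency and noise behaviour, not instrument effects the
generators omit: partial coherence, zone-plate point-spread, detector
nonlinearity, beam drift, or photometric mismatch between mosaic tiles.
Poisson counting noise is available as an option but Gaussian OD noise is
the default model.

## Numerical choices and conventions

* All indices are R-native 1-based `(row, col)`, origin top-left; the
  rotation center of a width-`W` sinogram defaults to `(W+1)/2`.
* Shepp-Logan is area-sampled (4× oversampling per axis) by default:
  partial-volume edges are what detectors record, and hard binary edges
  put an irreducible ~0.055 RMSE floor under any FBP at 128².
* Bicubic resampling is Catmull-Rom with edge replication; tomography
  sampling is bilinear with zero outside (air).
* Sample (n−1) standard deviation for `σ_pre`.
* Determinism: generators restore the caller's RNG state; ART ray order is
  fixed; identical seeds give bit-identical results end to end.

## Known limitations

* Parallel-beam only; no cone/fan beam, no phase-contrast reconstruction
  variants.
* Jitter correction assumes the specimen remains inside the field of view
  for its center-of-mass stage; use template tracking otherwise.
* The TIFF codec covers single-page uncompressed grayscale (uint16 /
  float32) — the beamline-export subset — not compressed or multi-page
  files.
* Principal component analysis of XANES stacks and photometric gain
  equalization between mosaic tiles are out of scope.
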