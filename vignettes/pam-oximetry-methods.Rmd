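---
title: "Photoacoustic mammography oximetry and microvessel morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photoacoustic mammography oximetry and microvessel morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamoxi)
```

`pamoxi` re-creates, on synthetic ground-truthed data, the computational
chain of a dual-wavelength photoacoustic mammography (PAM) study: forward
acoustic simulation of a compressed breast, universal back projection (UBP)
reconstruction, spectral unmixing into oxygen saturation (SO₂) maps, CD31
microvessel morphometry by block-wise total vessel perimeter (TVP), and the
cohort-level nonparametric statistics. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the synthetic validation demonstrates.

## Physical model

### Geometry and illumination

The breast is modeled mildly compressed between two plates along the z axis
(x is the lateral scan direction, y vertical). The detector array lies in
the plane z = 0; pulsed light enters from both plates. Because no laser pulse
energies are modeled, all pressures are in arbitrary "model units" — every
downstream quantity of interest (SO₂, ratios, positions) is invariant to that
scale.

Fluence uses a one-dimensional dual-sided diffusion-regime profile,

$$\Phi(z) = \Phi_0\left[e^{-\mu_{\mathrm{eff}} z} + e^{-\mu_{\mathrm{eff}}(L-z)}\right],
\qquad \mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a + \mu_s')},$$

with L the plate-to-plate thickness and the attenuation computed from the
phantom's *background* optics per wavelength (or supplied directly). This is
the simplest model consistent with estimating fluence from absorption and
scattering coefficients per wavelength; it ignores lateral diffusion and
boundary effects, which is acceptable for plate-compressed geometry at the
centimeter scales simulated. The same model is used for simulation and for
fluence compensation, so oximetry tests isolate reconstruction and unmixing
error rather than fluence-model mismatch.

### Chromophores and initial pressure

Each phantom structure (lesion sphere, vessel tube, subcutaneous vessel)
carries a total hemoglobin concentration (THC, mol/L) and a true saturation
`so2_true`, split as C_HbO = SO₂·THC and C_Hb = (1−SO₂)·THC. Absorption at
wavelength λ is
$\mu_a(\lambda) = \varepsilon_{HbO}(\lambda) C_{HbO} + \varepsilon_{Hb}(\lambda) C_{Hb} + \mu_{a,\mathrm{bg}}(\lambda)$
and the photoacoustic source is $P_0 = \Gamma \mu_a \Phi$ with the Grüneisen
parameter Γ = 0.20 (soft tissue at body temperature, configurable). The
operating pair 756/797 nm puts one wavelength on a deoxyhemoglobin absorption
peak and one near the isosbestic point, so the 2×2 extinction matrix is well
conditioned. The shipped extinction defaults are an approximate standard
compiled tabulation; they are a convenience only, and all package tests pass
ε explicitly so nothing depends on them silently.

### Acoustic forward model

Two forward paths are provided.

* **Voxel path** (`simulate_sinogram`): each nonzero voxel radiates the
  analytic N-shaped pulse of a uniform sphere of equivalent volume,
  $p(t) = P_0 (d - ct)/(2d)$ for $|d - ct| \le a$. This is exact per voxel
  (and is validated against retarded-time, linearity and determinism
  oracles), but an *extended* source assembled from voxel pulses carries
  rasterization granularity at the voxel transit scale. UBP's ramp-like
  $-2t\,\partial_t p$ term amplifies exactly that scale, and source
  supersampling (the `supersample` argument) reduces it only slowly — a
  property of the estimator, not a bug.
* **Analytic sphere path** (`simulate_sphere_sinogram`): the same closed form
  applied to whole uniform spheres. For spherical structures under uniform
  fluence this is the *exact* field, the classical validation source for
  back-projection algorithms, and it is what the physics round-trip
  uses. Inside the pulse, b(t) = 2p − 2t·dp/dt equals P₀ identically, so a
  normalized UBP recovers the true center amplitude for any aperture — which
  is why the round trip can demand machine-precision absorption recovery at
  sphere centers.

Array defaults mirror a clinical prototype: 15 × 23 = 345 elements at 2 mm
pitch (30 × 46 mm per scan position), 1 MHz central frequency, lateral scan
offsets for coverage up to 120 × 46 mm, 20 MHz sampling, speed of sound
1.54 mm/µs. Elements are points by default (finite aperture via sub-element
averaging is available in configuration); an optional Gaussian band-pass
mimics the transducer response but is off by default so the traces remain
analytically checkable.

## Reconstruction

`ubp_reconstruct` implements standard universal back projection: each voxel
accumulates $b(r_0, t = |r - r_0|/c)$ over element positions with planar
solid-angle weights $\cos\theta / d^2$, normalized by the summed weights
(toggleable). The time derivative uses central differences (one-sided at the
ends) and b is linearly interpolated at non-integer retarded times. Retarded
times outside the recorded window are skipped and counted, with a warning
above a configurable skip fraction — reconstructions should be run with
recordings that cover the grid. Multi-position scans are handled by
concatenating element positions before reconstruction.

Two numerical properties matter for interpretation:

* For a *compact* source (diameter of order the acoustic wavelength,
  1.54 mm at 1 MHz) the reconstructed maximum localizes the source center to
  within a voxel.
* For a *large* uniform sphere the reconstruction is flat-topped at the true
  P₀ with edge ringing just outside the boundary; the global maximum then
  sits on the ring, not the center. That is an artifact property, not a
  localization failure, and it is why the round-trip validation uses 1 mm
  radius spheres.

2-mm maximum intensity projections (`mip_slabs`) tile the volume into
consecutive slabs (the last may be thinner) and take per-pixel maxima, which
preserves the monotonicity required of a MIP.

## Oximetry

Absorption is recovered as $\mu_a = P_0 / (\Gamma\Phi)$, the two-wavelength
linear system is solved in closed form per voxel, and
SO₂ = C_HbO/(C_HbO + C_Hb) is evaluated only where THC exceeds a floor
(default 5% of the map maximum) — below it a voxel is *invalid*, not zero.
Negative concentrations and SO₂ outside [0, 1] are kept and counted rather
than clipped: saturations above 100% are a recognized artifact of pressure
and fluence estimation error and their frequency is itself informative. ROI
summaries (median, quartiles, mean) are computed over valid voxels only, and
an all-invalid ROI returns an explicit empty result. Contralateral-normal
ROIs are conventionally placed at the lesion ROI's depth; ROI placement is
always by explicit coordinates (no image registration is attempted).

The MIP signal classifier operationalizes qualitative reading criteria:
connected supra-threshold components with skeleton length ≥ 3 mm
(Zhang–Suen thinning, chain-length metric) and principal-axis elongation ≥ 3
are *vessels*; non-vessel components single-linkage clustered within 2 mm in
groups of ≥ 5 are *microvessel-rich*; stragglers remain unclassified. The
thresholds are configuration defaults chosen to separate the constructed
test fixtures — the underlying clinical criteria are qualitative, so these
numbers should be tuned on real data before any clinical use.

## Histomorphometry

Synthetic CD31 tiles default to 8,000 × 8,000 px at 0.42 µm/px, so one
0.84 × 0.84 mm analysis block is exactly 2,000 px and a tile is a 4 × 4
block grid. Vessels are rendered as filled disks, annuli (lumen boundaries
count toward perimeter, since endothelial staining surrounds the lumen) and
ellipses, with *analytic* perimeters recorded as truth; rendering uses a
fixed DAB-brown color inside the stain's HSI window on a background outside
it, and generation fails loudly if the two collide. RGB→HSI is the hexcone
convention (hue/saturation/value via `grDevices::rgb2hsv`, intensity = V),
fixed so masks are bit-reproducible. The operator's per-slide "optimal HSI"
choice is replaced by an explicit window shared between generator and
segmenter.

Perimeters use the 4-direction Cauchy–Crofton estimator,
$P = \tfrac{\pi}{8}h\,[N_0 + N_{90} + (N_{45} + N_{135})/\sqrt{2}]$, with
every foreground/background transition attributed to its foreground pixel.
That attribution gives two structural guarantees: block TVP sums conserve
the whole-mask total *exactly* (assignment is by pixel membership, so
boundary-crossing vessels split consistently), and component sums include
interior hole boundaries. Accuracy on digital disks is ~0.3% at r = 100 px
and under 2% at r = 20 px; axis-aligned rectangles are underestimated by up
to ~5%, a known Crofton bias. Components are 8-connected (EBImage's
4-connected labeling plus a diagonal merge pass). Lesional blocks are those
whose lesion-mask overlap fraction reaches a threshold (default 0.5), and
TVP/area = Σ selected block TVP / (count × 0.7056 mm²). An empty selection
yields an explicitly undefined ratio.

Tile extraction is half-open with zero-padded edge tiles and recorded pad
masks; the tile count follows the image size.

## Cohort statistics

The statistical layer wraps base R's tests behind a uniform result type and
the conventions of clinical statistical software: Pearson chi-square without
continuity correction (Yates available but off by default), Mann–Whitney U
exact for min(n) ≤ 8 without ties, Wilcoxon signed-rank exact for ≤ 20
nonzero differences without tied magnitudes (zeros dropped and counted,
classic convention), both otherwise using the tie-corrected normal
approximation *without* continuity correction, Kruskal–Wallis with tie
correction for ≥ 3 groups, and Pearson correlation with the t-transform
p value. Fully tied two-sample input returns p = 1 (the approximation is
0/0 there). Visibility accounting excludes benign lesions before any rate
is computed and reports numerators and denominators per histology class.

The synthetic cohort generator mirrors a 39-lesion series: 33 invasive and
6 in-situ lesions, visibility probability 29/39, CAIX positivity 11/33
confined to invasive cases, therapy history 13/39, subcutaneous SO₂ baseline
0.85 with a −0.15 lesional shift and −0.03 contralateral shift, and
per-measurement noise SD 0.08 — values chosen once to reflect the magnitudes
a clinical PAM series reports. Under these conditions the paired signed-rank
test is calibrated (type-I error ≈ 0.05 over 2,000 null replicates) and has
essentially full power against the −0.15 shift at n = 39, so the cohort
simulation reproduces the decisive lesion-vs-reference SO₂ separation such
studies observe. The lesional TVP/area covariate is log-normal
(meanlog = log 6, sdlog = 0.55), matching the right-skewed few-µm/mm²-scale
medians clinical tables report — though note that scale is not directly
comparable to the µm/mm² this package computes on synthetic slides, where
the normalization of the published values is not recoverable.

## Pipeline, determinism and problem sizes

`run_pipeline` executes simulate → reconstruct → oximetry → histology →
cohort from a validated config (R list, YAML or JSON), writing all artifacts
plus a manifest with a key-order-stable config hash. One global seed fans
out as `seed × 100 + stage ordinal`, so stages are independently
reproducible; reruns with identical config and seed are bit-identical.
`make_report` renders a timestamp-free markdown report (byte-stable under
regeneration) with an SO₂ box plot, a TVP block heat map and the cohort test
table, flagging absent artifacts instead of failing.

Default validation sizes are chosen so the whole chain runs in seconds to a
few minutes on one CPU: the round-trip phantom is 64³ voxels at 0.5 mm pitch
(a scaled-down grid at the clinical array's full 345-element geometry), the
demo pipeline 40³ voxels, synthetic slides 2,000 px where a full 8,000 px
tile is not the point, and the unmixing oracle 10⁵ voxels. These are choices
about validation economy, not model limits; all sizes are configuration.

## What the synthetic validation does and does not show

Passing tests demonstrate that the implementation is internally correct:
the forward model obeys retarded-time physics and linearity, UBP recovers
position and (for analytic sphere data) exact center amplitudes, unmixing is
an exact inverse, perimeter and block accounting agree with analytic truth
and conserve exactly, and the statistics are calibrated. They do *not*
demonstrate clinical performance: real breasts have heterogeneous optics and
acoustics (the fluence model here is 1-D, the sound speed uniform), real
transducers band-limit and have finite apertures and calibration error,
patients move between the two wavelength acquisitions (~90 s apart; no
motion model is implemented), real CD31 slides have stain variability,
texture and operator-dependent HSI windows, and published TVP/area scales
are not reproducible from their description. Absolute pressure units are
arbitrary throughout. The package is a validated scaffold for method
development and power analysis, not a clinical device model.
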