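---
title: "Layered fusion reconstruction for multi-conductivity EIT: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered fusion reconstruction for multi-conductivity EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `eitlf`, the parameters that
matter, and the design decisions taken where the method left room for
interpretation. It is the place to look before trusting the package on data
that differ from its simulation setting.

## Forward model

The forward solver computes boundary voltages for a known conductivity
distribution on a circular 2D domain (default radius 0.20 m) with `nE = 16`
boundary electrodes of 1 cm arc width. It uses linear (P1) triangular
finite elements with the **complete electrode model**: electrodes have
finite width and a contact impedance (default 1e-5 Ω·m², configurable per
electrode), carry a prescribed net current, and are otherwise
equipotential. Electrode voltages are extra unknowns; a Lagrange multiplier
grounds the system by forcing them to sum to zero. The quasi-static model
is real-valued: the excitation frequency (100 kHz in the motivating
setting) enters only through the tissue conductivity values.

The mesh is a deterministic triangulation built from concentric node rings
(`disk_mesh()`): ring *i* of *K* carries `16·i` nodes, so the mesh is
*exactly* invariant under rotation by one electrode pitch. This makes
reciprocity and rotation checks sharp to near machine precision instead of
mesh-limited. Ring radii follow `R·(i/K)^0.8`; the mild grading refines the
boundary region where the drive current concentrates. `disk_mesh()`
defaults to `K = 16` (4096 elements), for which a doubling of the
resolution changes homogeneous-disk voltages by well under 1%. The *study*
default (`study_config()`) is `K = 24` (9216 elements): the layered
pipeline subtracts two nearly equal voltage vectors, and the residual is
sensitive to discretization error that the raw voltages tolerate —
with 4096 elements one of the six phantom cases shows a visible
discretization artifact in the anomaly layer that disappears at 9216 and
stays gone at 16384.

The adjacent protocol drives every neighbouring electrode pair in turn
(5 mA default) and reads every neighbouring pair not involved in the drive,
in ascending index order: `nE·(nE−3) = 208` values per frame. Only half are
independent by reciprocity; the package keeps all of them, as acquisition
systems do.

## Sensitivity and the pixel raster

The Jacobian of the measurements with respect to element conductivities is
assembled by the adjoint method: for drive field `u_d` and measurement
field `u_m` (the unit-current field of the measurement pair),
`∂V/∂σ_e = −I·area_e·∇u_d·∇u_m`. Element sensitivities are aggregated to
the 32×32 raster through area-overlap weights (`pixel_weights()`,
approximated by a 9-point barycentric subdivision of each triangle; rows
sum to 1). Pixels whose centre falls outside the disk are excluded; the
support holds M = 812 pixels. The same weights convert a pixel-level
conductivity perturbation into element values, which keeps the
finite-difference check of the Jacobian self-consistent (agreement is ~0.1%
against brute-force forward perturbations, tested to 1%).

`normalize_sensitivity()` rescales each column to unit sum — the convention
under which a uniform change α over n pixels satisfies
`mean(ΔU) = α·n/N`, the identity behind the fusion weights. Signed sums are
the default; for the reference setup all column sums are strictly positive,
and a degenerate (near-zero) sum raises an error naming the pixel rather
than silently amplifying it. An absolute-sum mode exists for scenes with
mixed-sign columns.

## Phantoms and noise

The six study phantoms emulate a transverse chest section: two elliptical
lungs (0.27 S/m, a deflated-lung value at 100 kHz) and one circular lesion
(0.6 S/m — 2.2× the lung value, within the 1.6–3.3 range reported for lung
tumours) inside the right lung. Three lesion radii {0.10, 0.15, 0.20}·R are
placed at the lung centre (cases 1–3) and at an upper-inner position
(cases 4–6). All geometry lives in `lung_geometry()` and is expressed in
fractions of the domain radius:

* lungs: semi-axes (0.38, 0.58)·R centred at (±0.47, 0)·R. These were
  chosen so the lungs are clearly separated — ellipses wide enough to touch
  at the midline would merge into a single connected region on the raster
  and stop being "two main objects".
* the **background** (reference) conductivity is 0.17 S/m. The simulation's
  background is not uniquely pinned down by the motivating setting; we fix
  it so that the lung-versus-background step is ≈0.1 S/m, the scale quoted
  for the main-object layer's contrast, and so that both the lungs and the
  lesion are *positive* contrasts — the quarter-amplitude layer extraction
  assumes the main objects dominate the positive side of the pre-image.

`add_noise()` adds zero-mean white Gaussian noise to the voltage-*change*
frame, with power set from the frame's own mean square so that
`SNR = 10·log10(Pu/Pnoise)` matches the nominal level; the draw is
reproducible from an integer seed and leaves the caller's RNG state
untouched. The generator realizes the nominal SNR to ±0.5 dB on average
(tested over 1000 draws).

What the phantoms do *not* emulate: thorax-shaped (non-circular)
boundaries, anatomical organ shapes, electrode movement or contact drift,
frequency-dependent complex admittivity, and model error between the
simulation mesh and reconstruction mesh beyond discretization (the same
mesh family generates data and Jacobian). Passing the simulation panel
therefore demonstrates the algorithmic behaviour of layered fusion, not
clinical performance.

## The layered pipeline: decisions in the open points

**Which matrix where.** The layered chain (`run_lf()`) uses the matrix the
caller passes, and the study passes the **raw physical Jacobian**: step 3
predicts a real voltage vector (`ΔŨ₁ = a·S·Δσ̃₁`), and a per-column
rescaled matrix distorts that prediction pixel by pixel, which leaks
main-object signal into the anomaly layer. The one-step TK *baseline* uses
the column-normalized matrix — the stronger and more standard baseline, as
normalization compensates the centre-versus-boundary sensitivity decay.
The fusion-weight identity is exact for column-normalized data and is
tested there; on raw data the weights are per-layer averages in the same
voltage units, and only their ratio matters for the fused image.

**Signed versus absolute means.** The weight formula
`δσ = N·mean(ΔŨ)/n` is stated for an idealized positive layered model,
where the arithmetic mean and the mean of absolute values coincide. On
simulated (nonlinear) data the *signed* mean of the small layer-2 residual
is near zero with unstable sign, which flips the sign of the fused anomaly
from run to run. `fusion_weights()` therefore defaults to the absolute
mean (`mean_mode = "absolute"`); the signed mode is available and is the
right choice for strictly model-generated data. The cost of the absolute
mode is that a truly anomaly-free scene still receives a nonzero layer-2
weight (the fused image remains dominated by layer 1, but the residual is
not suppressed to zero as in signed mode).

**Regularization parameter.** Both Tikhonov steps inside one layered run
share a single λ, resolved once per run. The default when none is given is
`1e-3·trace(SᵀS)/M`, a dimensionless scale on the matrix at hand;
`select_lambda_lcurve()` implements corner selection by maximum Menger
curvature of the (log residual, log solution norm) curve over a candidate
grid, falling back to the median candidate with a warning when the curve
has no corner. The study selects λ in advance by the L-curve on the first
noise-free case — once per matrix — and then uses it uniformly across
cases, noise levels and methods.

**Other fixed points.** The ¼-amplitude thresholds operate on signed values
(positive-contrast scenes; an absolute-value polarity flag exists). The
low-sensitivity index set of both scale evaluations in step 3 is the one
induced by the *total* change ΔU; an empty set (flat `|ΔU|`) falls back to
all indices with a warning. The proportional filter breaks ties at the
cut-off by lowest pixel index (stable descending sort). The layer-2 image
is max-normalized before counting its working pixels, and `n₂` is the
ceiling of its sum, at least 1.

## Evaluation conventions

`relative_error()` is the bare norm ratio `‖Δσ̃−Δσ‖/‖Δσ‖`.
`evaluate_reconstruction()` compares **amplitude-normalized** images (both
reconstruction and truth scaled to unit maximum): one-step difference
images recover the conductivity change only up to an overall scale, so an
unnormalized comparison would measure little but that arbitrary scale. The
anomaly object is extracted by the ¼-amplitude rule — from the full image
for one-step reconstructions (which is exactly why their size error is
huge: the extracted object is the whole lung region), and from the
**layer-2 component** for layered results, where the anomaly is an explicit
separate layer. Centroids are intensity-weighted over the extracted mask;
the position error is reported in pixels and as a percentage of the
32-pixel image width.

## Known limitations

* The layer-2 image of a deep 2–4 cm lesion is intrinsically blurred over
  several times its true pixel count. The ¼-amplitude (FLF) filter keeps
  that halo, so FLF's size error is large even when localization is good,
  and the halo keeps FLF's whole-image relative error close to the
  baseline's — on this panel FLF improves RE only marginally and not in
  every case, while PLF (with the true area prior) improves it in all six
  cases and roughly halves the mean. Ceiling experiments with the exact
  layer-1 voltage show this is a property of the filtered layer-2 blur,
  not of the layer-1 estimate.
* At 40–80 dB SNR the TK baseline's (normalized) RE is almost entirely
  structural error and barely responds to noise, while the proportional
  filter's top-`t` selection is discontinuous in the data; across that SNR
  range PLF's mean-RE spread is comparable to TK's rather than smaller.
  Robustness claims should be read against that observation.
* The scale relation behind step 3 assumes the anomaly hardly moves the
  low-sensitivity measurements; no quantitative breakdown threshold is
  known, and for large or shallow anomalies the assumption degrades
  (visible as mirror-image artifacts in the anomaly layer).
* Two layers only: scenes with more than three conductivity phases are out
  of scope.

## Problem sizes used by the test suite

Unit tests run on reduced meshes (1024–2304 elements) where the properties
under test are mesh-independent; the panel-level checks and the acceptance
script use the full study configuration (9216 elements, six cases, 208
measurements, 812 pixels), and the noise study uses SNR ∈ {40,…,80} dB
with five seeds per level.
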