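# eitlf — layered fusion reconstruction for multi-conductivity EIT

Electrical impedance tomography (EIT) reconstructs the conductivity
distribution inside a body from boundary voltages measured while small
currents are driven through surface electrodes. Linear one-step methods such
as Tikhonov regularization work well for two-phase scenes (e.g. lungs
against a thoracic background) but fail when a *third* conductivity phase is
present — a lesion inside a lung — because the small local change is
swallowed by the dominant organ signal.

`eitlf` implements a layered fusion (LF) strategy for this
multi-conductivity setting, together with everything needed to study it end
to end in simulation: a complete-electrode-model finite element forward
solver on a circular 2D domain, adjacent-protocol measurement simulation,
adjoint-method sensitivity (Jacobian) matrices on a 32×32 pixel raster,
lung-like phantoms with lesions, additive Gaussian noise at prescribed SNR,
and the standard image quality metrics.

## The method

Difference imaging linearizes the forward map around a reference
conductivity: `ΔU ≈ S Δσ`, with `S` the N×M sensitivity matrix
(N = nE(nE−3) adjacent-protocol measurements, M supported pixels). One-step
Tikhonov (TK) solves

    Δσ̃ = (SᵀS + λI)⁻¹ Sᵀ ΔU .

Layered fusion decomposes the scene into a *main-object layer* (the lungs)
and an *anomaly layer* (the lesion):

1. **Pre-image** — one-step Tikhonov on the full change `ΔU`.
2. **Layer-1 extraction** — binarize the pre-image at ¼ of its maximum;
   this captures the main objects, whose outline barely changes when a
   small anomaly appears. A known organ contour can be supplied instead.
3. **Layer-1 voltage** — the binary layer is scaled by a factor `a` fixed
   on the *low-sensitivity range*: the measurements with `|ΔU|` below half
   the mean absolute change, which a small local anomaly hardly perturbs.
   Then `ΔŨ₁ = a·S·Δσ̃₁`.
4. **Layer-2 voltage** — `ΔŨ₂ = ΔU − ΔŨ₁`, exactly.
5. **Layer-2 image** — Tikhonov on `ΔŨ₂`, sharpened either by the same
   ¼-amplitude filter (**FLF**, no prior needed) or, when the anomaly's
   area fraction `p` is known, by keeping the `⌊p·M⌋` largest pixels
   (**PLF**).
6. **Fusion** — each layer receives a weight from the mean of its voltage
   change (`δσ = N·mean(ΔŨ)/n` over the layer's `n` working pixels) and the
   layers are summed: `Δσ̃′ = δσ₁Δσ̃₁ + δσ₂Δσ̃₂″`.

Reconstructions are scored by relative image error
`RE = ‖Δσ̃−Δσ‖/‖Δσ‖` (on amplitude-normalized images), and by the size
error `SE = |m′−m|/m` and position error `PE = ‖r′−r‖` of the anomaly
object extracted by the same ¼-amplitude rule.

## Worked example

```r
library(eitlf)
library(dplyr)

cfg <- study_config(snr_db = NULL)   # the noise-free six-case study
sys <- study_system(cfg)             # mesh, protocol, Jacobian (~10 s)
panel <- run_study(cfg, sys = sys)   # TK / FLF / PLF on all six phantoms

panel |>
  group_by(method) |>
  summarise(mean_re = mean(re), min_se_pct = 100 * min(se),
            min_pe_pct = min(pe_pct))
#>   method mean_re min_se_pct min_pe_pct
#> 1 flf      1.29        272.      9.84
#> 2 plf      0.628         0       0.104
#> 3 tk       1.29        925      18.5
```

The one-step baseline cannot isolate the lesion: its ¼-amplitude object is
the whole lung region, so its best-case size error is 925% and its best
position error 18.5% of the image width. The prior-informed layered variant
(PLF) recovers the lesion's pixel count exactly (SE 0%) and its centroid to
a tenth of a percent of the image width in the best case, and halves the
mean relative error of TK.

A single reconstruction exposes all intermediates:

```r
sim <- simulate_case(sys, case_id = 3)             # lesion in the right lung
fit <- run_lf(sim$dU, sys$S,
              reg_config(lambda = panel$lambda_lf[1]), p = sim$p_true)
fit
#> <lf_result PLF> a = 0.09157, weights (0.0001408, 0.0002712),
#>                 n1 = 293, n2 = 23, lambda = 7e-09
evaluate_reconstruction(fit, sim$truth, sim$truth_anomaly)
#>     re se pe_px pe_pct m_rec m_true
#> 1 0.56  0   1.6   4.99    32     32
autoplot(fit)    # pre-image, layers, fused reconstruction
```

`glance(fit)` returns the scale factor and fusion weights as a one-row
tibble; `tidy(fit)` gives a per-pixel long table for custom plotting.

A file-based pipeline (`cmd_simulate()`, `cmd_reconstruct()`,
`cmd_evaluate()`, or the thin CLI in `inst/cli/eitlf.R`) writes frames,
images and metric tables as CSV/JSON for use outside R.

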