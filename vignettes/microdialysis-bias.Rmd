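---
title: "Modelling the glucose-removal bias of microdialysis in skeletal muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the glucose-removal bias of microdialysis in skeletal muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdbias)
```

## The problem

Microdialysis is the standard technique for measuring interstitial glucose
concentration (IGC) in muscle: a semi-permeable probe is perfused with fluid,
interstitial glucose diffuses into the perfusate, and the IGC is inferred
from the dialysate concentration and the probe's relative recovery. The
probe, however, continuously *removes* glucose from the very tissue it
samples — at roughly 2e-11 mol/s for typical probe settings, the supply of
hundreds of thousands of capillaries. `mdbias` implements two coupled
models that quantify what this removal does to the measurement:

1. a steady-state **three-compartment model** (plasma, endothelium,
   interstitium) on a conical Krogh-type tissue domain, predicting the
   unperturbed IGC `Ci,0` from tissue blood flow and metabolism; and
2. a radial **reaction–diffusion model** of the interstitial field around
   the probe, whose solution gives the effective concentration `Ci,eff` at
   the membrane, the bias amplitude `alpha`, its time course, and the
   resulting bias in recovery calibration and in apparent
   permeability–surface (PS) products.

## The compartment model

Within a cone of tissue supplied by one capillary (radius tapering linearly
from `rt_a = 28 um` at the arterial end to `rt_v = 22 um` at the venous
end), glucose moves by diffusion only. Integrating the axial supply balance
gives the mean plasma profile `C̄(ξ)`; its endpoint is pinned to the venous
concentration by mass conservation, `F (Ca − Cv) = M`. One transcription
subtlety is worth recording: the per-capillary supply constant has
inconsistent dimensions if taken at face value, so the implementation
re-derives the axial profile by normalizing the per-capillary plasma flow
with the cone's annular tissue volume. Under that normalization the
(unknown) capillary length cancels and `C̄(1) = Cv = Ca − M/F` holds
exactly, which the tests assert rather than trusting any transcribed
polynomial.

Radially, three nested resistances connect plasma to interstitium:

* a plasma drop `M (rt² − rw²)/(8 Dp)` — about 1e-5 mM at rest, negligible;
* the endothelial drop `M (rt² − rw²) ln(rw/rp)/(2 Dw)` — about 0.2 mM at
  rest, and the only term that matters because `Dw ≈ 4.5e-14 m²/s` is four
  orders of magnitude below free diffusion; it scales linearly with
  metabolism (3 mM at a 15-fold, hyperinsulinemia-like increase);
* an interstitial drop of order 5e-4 mM — negligible at any realistic
  metabolism (still below 0.05 mM at 100-fold basal).

The quick estimate `Ci,0 = (Ca + Cv)/2 − M (rt² − rw²) ln(rw/rp)/(2 Dw)`
(evaluated at the midpoint radius `rt = 25 um`) therefore agrees with the
full chain of profiles to a few hundredths of a mM; both give
`Ci,0 ≈ 4.7 mM` at rest. Scalar outputs use the axial midpoint `ξ = 0.5`,
whose plasma term equals `(Ca + Cv)/2`; this choice is validated by numeric
agreement, as the reference account does not state its evaluation position.

`Dw` itself is calibrated, not taken from first principles: `calibrate_dw()`
finds the wall coefficient whose simulated plasma-to-interstitium tracer
equilibration time (95% of a step, by default — the criterion is exposed as
a parameter because the experimental "equilibrium" is not defined more
precisely) matches an observed time. The default `4.50e-14 m²/s`
reproduces the reported ~15 min equilibration in muscle; the calibration's
contract is its round-trip identity (`equilibration_time(calibrate_dw(t)) =
t` within 1%), not any absolute figure.

## The probe-bias model

Glucose removed at the membrane is resupplied by capillaries. Linearizing
the compartment model around the unperturbed state, the local resupply rate
is `γ(r) = (Ci,0 − Ci(r))/A`, where the timescale

`A = 1/(2F) + (rt² − rw²) ln(rw/rp)/(2 Dw)` (≈ 750 s + 1470 s at rest)

combines plasma depletion and trans-endothelial transport. The steady field
then obeys a modified Helmholtz equation with screening length
`λ = sqrt(Di Vi A) ≈ 0.64 mm`, a Robin (uptake) condition at the membrane
`Di Vi dCi/dr = β (Ci(r1) − Cp)` with `β = R0 f / S_probe ≈ 6.6e-7 m/s`,
and the unperturbed value far away. Its decaying solution is
`Ci(r) = Ci,0 + B K0(r/λ)`; the closed form is the primary solution path
(no discretization error in reported numbers), and an independent
finite-volume solver on a log-spaced grid (`solve_steady_fd()`, ≥2000
nodes) is kept as a numerical cross-check — the two agree to better than
0.1% across the full flow-and-β sensitivity sweep. One sign in the printed
membrane condition is flipped relative to the field's own monotonicity (it
encodes the into-the-probe flux direction); the implementation uses the
physically consistent orientation, under which the field rises from
`Ci,eff` at the membrane to `Ci,0` far away.

Because the problem is linear, the bias is fully characterized by one
number: `Ci,0 − Ci,eff = alpha (Ci,0 − Cp)`. At the standard parameters
`alpha ≈ 0.54`: with `Ci,0 = 4.7 mM` and `Cp = 2 mM` the probe reads
`Ci,eff ≈ 3.25 mM`, a ~31% underestimation confined to a cylinder of
roughly 1–2 mm radius. Raising `Cp` to 3.3 mM halves the driving
difference and hence the bias (`Ci,eff ≈ 3.95 mM`). The removal rate is
`R0 f (Ci,eff − Cp) ≈ 2.1e-11 mol/s`; note that the reference worked
example prints a removal rate about 10–15% above what its own printed
`Ci,eff` implies through this same formula, an internal inconsistency the
package does not attempt to tune away.

The sink term uses the representative radius `rt = 25 um` (the cone
midpoint), consistent with the compartment model's scalar outputs. The
outer boundary default `r2 = 50 r1 = 12.5 mm` is ~20 screening lengths;
`solve_steady()` refuses to report a solution whose far field has not
decayed there.

## Transient behaviour and the storage term

After removal onset the field relaxes from `Ci ≡ Ci,0` to the screened
steady profile. The time-dependent equation is integrated by method of
lines (stiff `lsoda`, banded Jacobian, the same log-spaced grid as the
finite-volume solver). The storage term deserves a note: appending the bare
time derivative to the removal/resupply balance (`dCi/dt = Di Vi ∇²Ci −
(Ci − Ci,0)/A`, "unit" storage) reproduces the reference characteristic
times — 124 s at β0, 278 s at 0.25 β0, 23 s at 4 β0 against the published
120/270/24 s. The per-tissue-volume variant `Vi dCi/dt = …`, which a
strict bookkeeping of interstitial content would suggest, simply rescales
time by `Vi` and lands a factor of five away from those times; it remains
available via `storage = "interstitial"` for sensitivity analysis, but the
unit form is the default because it is what the reference dynamics actually
follow.

The membrane drop is not single-exponential: the far annulus relaxes last,
on the resupply timescale `A`. The published "time to steady state"
(10/22/2 min across the β sweep) corresponds to ~4.6–5 characteristic
times, i.e. the 99%-completion time *of an exponential* with the measured
`tau`; the directly measured 99% crossing of the simulated drop is several
times longer because of that slow tail. `steady_state_time()` therefore
defaults to the exponential convention `ln(100) · tau` and exposes the
measured crossing via `method = "measured"`.

## Calibration bias and correction

Recovery calibration is itself biased by removal. For the no-net-flux
technique, the dialysate concentration stays *exactly* linear in the
perfusate concentration even while the probe depletes the tissue — the
slope is `1 − R0 (1 − α̃)`, so regression returns `Rm = (1 − α̃) R0`,
with `α̃ = alpha_t(wait_time)` the bias amplitude at the moment the
calibration samples are taken. The internal-reference technique is biased
identically (within a percent) because the accumulating tracer field
mirrors the native removal problem; the metabolic tracer sink
`M Ci*(r)/Ci(r)` shifts the steady tracer ratio from `alpha` by only about
1%. The measured IGC combines the two biases,

`Ci,m = [(1 − α) Ci,0 + (α − α̃) Cp] / (1 − α̃)`,

and always lies between `Ci,eff` (instant calibration, `α̃ = 0`) and
`Ci,0` (fully settled calibration, `α̃ = α`, where the two biases cancel
exactly). `correct_igc()` is the exact algebraic inverse, turning a
measured value back into an estimate of the true concentration. The
internal-reference expression assumes the tracer is at trace level relative
to native glucose; the package documents it as valid only in that regime.

Finally, `ps_true()`/`ps_measured()` propagate concentrations into the
apparent endothelial PS product `PS = −F ln[(Cv − Ci)/(Ca − Ci)]`. PS is
increasing in `Ci` on its domain, so underestimating IGC underestimates
PS — and because the *relative* bias shrinks as `Ci,0` falls toward `Cp`
under high metabolism, the biased `PS_m` rises between rest and
insulin-stimulated conditions much more steeply than the true PS does.
When `Ci ≥ Cv` the expression is undefined ("elevated extraction") and the
package raises a labelled error rather than returning a number.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `F` | 4 | mL/100 mL/min | resting muscle blood flow |
| `M` | 0.8 | µmol/100 mL/min | basal glucose metabolism |
| `Ca` | 5 | mM | arterial glucose (euglycemia) |
| `Vi` | 0.2 | — | interstitial volume fraction |
| `Di`, `Dp` | 9.2e-10 | m²/s | free glucose diffusion |
| `Dw` | 4.50e-14 | m²/s | endothelial wall coefficient (calibrated) |
| `rp`, `rw` | 2.5, 3.1 | µm | capillary plasma / outer-wall radius |
| `rt_a`, `rt_v` | 28, 22 | µm | tissue cone radii |
| `R0` | 0.5 | — | true relative recovery |
| `f` | 3.33e-11 | m³/s | perfusate flow (2 µL/min) |
| `L`, `r1` | 16, 0.25 | mm | probe membrane length / radius |
| `Cp` | 2 | mM | perfusate glucose |

All defaults are overridable individually or through a YAML/JSON config
(`read_params_config()`). `Di` is exposed as-is: whether tissue tortuosity
is already folded into the literature value is not stated at the source, so
no additional tortuosity factor is applied. mM and mol/m³ are treated as
the same unit throughout.

The scenario presets include four isocontour-map quarters with assumed
true concentrations 4.7/4.1/3.5/2.9 mM — chosen to span the range between
resting and strongly insulin-stimulated states at fixed flow — and a
literature-probe demonstrator (`R = 0.3`, `f = 4.17e-11 m³/s`,
`Cp = 1.5 mM`) for which tissue-side flow and metabolism must be supplied
by the user, since they are study-specific inputs.

## Numerical choices

* Radial grids are log-spaced from `r1` to `r2 = 50 r1`; the steady
  finite-volume oracle uses ≥2000 nodes, the transient solver 200 (the
  characteristic time changes by <2% between 120 and 280 nodes).
* Transient problem sizes in the test-suite and the acceptance script
  (200 radial nodes, windows of 3600–7200 s) were chosen as the smallest
  grids whose characteristic times are grid-converged to ~1%.
* The equilibration solver uses harmonic-mean interface diffusivities
  across the wall/interstitium jump and a Dirichlet plasma node, with the
  interstitial capacity `Vi` carried explicitly.
* Degenerate inputs: `Ci,0 = Cp` yields a uniform field and zero removal
  (with `alpha` still reported from the closed form); `β → 0` recovers the
  unbiased probe; `M/F ≥ Ca` ("complete extraction"), `Ci ≥ Cv`
  ("elevated extraction") and an unconverged outer boundary are errors,
  not silent numbers.
* Concentrations are never clamped; a negative field value (possible only
  outside the linear model's validity) would raise a warning.

## What the synthetic scenarios do and do not show

`generate_fixtures()` draws seeded Latin-hypercube sweeps over
`(Ci,0, Cp, β, F, M)` in the ranges spanned by the sensitivity analyses
(2–8 mM, 0–2 mM, 0.25–4 β0, 1–40 mL/100 mL/min, 0.8–12 µmol/100 mL/min).
These sweeps exercise the model's invariants — linearity in the driving
difference, monotone sensitivity to β and F, mass conservation — under
idealized conditions: homogeneous tissue, constant `Dw` per run, no
insertion trauma, no convective interstitial transport, an infinite
cylindrical probe without tip effects. Passing them shows the solvers
honour the model; it does not validate the model against real tissue,
where endothelial permeability likely rises with metabolism and probe
insertion transiently disturbs the tissue.

## Known limitations

* Constant `Dw` per run: conditions of elevated metabolism in the
  literature suggest an adaptive endothelial permeability; the package
  leaves this to the user as an explicit parameter change.
* The linear removal model loses validity if the probe could drive
  concentrations negative (very large β with low `Cp`).
* Predictions for specific published studies require that study's flow,
  metabolism and probe parameters; the machinery accepts them, but no
  study-specific numbers ship with the package beyond the probe-parameter
  demonstrator preset.
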