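---
title: "Modelling single-turnover kinetics of the bacterial luciferase reaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-turnover kinetics of the bacterial luciferase reaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxkin)
```

## The reaction and its model

Bacterial luciferase is a flavin-dependent monooxygenase that emits light
while oxidizing reduced flavin mononucleotide (FMNH2) and a long-chain
aldehyde. In the single-turnover assay, an air-equilibrated luciferase
solution is rapidly mixed with FMNH2 and decanal in a stopped-flow
instrument. Because free FMNH2 autoxidizes within a fraction of a second,
each enzyme molecule turns over at most once, and the light output is a
flash: a rise within about a second, a peak, and a decay over 8–10 s.

`luxkin` tracks the canonical reaction scheme as a system of ODEs over the
species (all concentrations in µM):

* `F` free FMNH2, `E` free luciferase, `A` free decanal;
* `I1` = E·FMNH2 (Intermediate I), formed at the bimolecular rate `k1` (and,
  in an opt-in variant, dissociating at `km1`);
* `I2` = E·FMNHOOH, the C(4a)-hydroperoxyflavin (Intermediate II), formed
  from `I1` at the pseudo-first-order rate `k2` — oxygen is folded into `k2`
  because assays run at ~120 µM dissolved oxygen, far above the other
  reactants, so no oxygen state is carried;
* `I2A` = E·FMNOOH·RCOH (Intermediate IIA), formed by reversible aldehyde
  binding (`k3`, `km3`);
* the catalytic step `k4` converts `I2A` into the electronically excited
  emitter; the observable intensity is proportional to this flux,
  `I(t) = scale · k4 · I2A(t)`.

Two dark pathways compete with light production: autoxidation of free FMNH2
(`kd`) and dark decay of Intermediate II to FMN and H2O2 (`kdd`). Product
species (FMN, acid, H2O2, released enzyme) are not tracked individually;
instead two cumulative sinks (`Sd`, `Sdd`) and the emitted-quanta proxy `Q`
close the books, so that enzyme (`E + I1 + I2 + I2A`) and flavin
(`F + I1 + I2 + I2A + Q + Sd + Sdd`) are conserved exactly. The tests verify
both to below 1e-6 relative drift along full trajectories.

Units: bimolecular constants are interpreted in 1/(µM·s). With the
characterized buffer constants (`table1_presets()$buffer`) this convention
reproduces the observed flash shape — peak near 0.3 s, free FMNH2 below 2%
of its initial value by 0.5 s, tail decay constant between `kdd` and
`kdd + k4`. A literal per-molar reading would make the reaction about six
orders of magnitude too slow to produce any of those features.

## Numerical integration

The rate span is wide — `k2 ≈ 400` 1/s against `k4 ≈ 0.5` 1/s — so the
system is stiff. `simulate_curve()` integrates with `deSolve`'s `lsoda`
(implicit BDF when stiff, internally generated Jacobian) at `rtol = 1e-8`,
`atol = 1e-10` µM, with the right-hand side compiled in C for speed; a pure-R
reference implementation (`lux_rhs()`) is exported and tested against the
compiled path. Tightening tolerances a hundredfold moves trace points by
less than 0.1% of the peak. The default grid is 0–15 s at 1 ms, the standard
acquisition window of the stopped-flow assay; tests that do not probe
integration accuracy use 10–20 ms grids, which changes extracted features by
well under 1%.

## Empirical curve parameters

`extract_features()` computes the four conventional descriptors of a flash
curve: peak intensity `Imax`; total quantum yield `Qstar` as the trapezoidal
area under the curve (no smoothing assumptions); initial velocity `v0` as
the OLS slope of the rise from `t = 0` until the signal first reaches 20% of
`Imax`; and decay constant `kdecay` from a log-linear regression of the tail,
starting where the signal first falls to 50% of `Imax` after the peak.
The 20% and 50% thresholds are conventions — the "starting linear part" and
"final part" of a flash curve are not sharp boundaries — and both are
arguments, so sensitivity to the choice can be checked directly. Points at
or below zero are excluded from the log-linear tail fit, which keeps the
estimator defined for noisy tails.

## Global fitting and identifiability

`fit_global()` recovers one shared set of `{k1, k2, k3, km3, k4}` from a
family of curves measured at several aldehyde concentrations (canonically
10, 20, 30, 40, 50 µM decanal with 0.95 µM enzyme and 15 µM FMNH2) in one
medium. The dark rates `kd` and `kdd` come from separate experiments and are
held fixed. The objective is the plain summed squared intensity residual
over all curves with uniform weights, minimized by bounded
Levenberg–Marquardt (`minpack.lm`) in log-parameter space; bounds are
`k1, k3 ∈ [1e-4, 1e2]` 1/(µM·s), `km3 ∈ [1e-3, 1e3]` 1/s,
`k2 ∈ [10, 5000]` 1/s, `k4 ∈ [1e-3, 1e2]` 1/s. Intensities are in arbitrary
units, so a scale convention is required; the generator and fitter share one
fixed `scale` (default 1), which makes synthetic recovery well-posed. For
real data a per-family scale could be co-fitted; that is deliberately not
the default.

Two structural features of the model shaped the optimizer design:

* **`k2` is weakly identified.** Intermediate II formation is not
  rate-limiting, so luminescence curves constrain `k2` only loosely (the
  package's own recovery tests bound it within ~20%, against 2% for the
  other constants). Its starting value should come from the independent
  absorbance experiment: `fit_k2_exponential()` fits
  `D380 = A·exp(-k2·t) + B` to the 380-nm decay recorded over ~15 ms,
  recovering `k2` to 0.1% on clean data.
* **Ridges produce local minima.** Along one ridge `k2` collapses toward a
  bound while `k3`, `km3`, `k4` compensate (only the effective flux
  `k3·k4/(km3 + k4)` is strongly constrained when aldehyde binding
  pre-equilibrates). Each optimizer start therefore runs in two phases:
  first the four identifiable constants with `k2` pinned at its start, then
  all five released from the phase-1 endpoint. On noiseless
  self-consistency problems this recovers every characterized medium —
  including 40% sucrose, the hardest, with its slow aldehyde binding and
  fast catalysis — to machine precision from starts perturbed by tens of
  percent. Multi-start (default 8 starts, log-uniform perturbations up to a
  factor of 5 on `k1, k3, km3, k4`; `k2` never perturbed, for the same
  identifiability reason) guards the nonconvex landscape, with seeds
  recorded and the best start returned.

Fit quality is reported two ways, matching how stopped-flow fits are judged:
a per-curve normalized root-sum-of-squares relative error
(`relative_error()`), and the maximum pointwise relative deviation over
0.2–5 s (`window_deviation()`), the window that carries the bulk of the
reaction time course. Both are invariant to a common rescaling of model and
data.

### Reversibility of flavin binding

The default model treats flavin binding as irreversible. The dissociation of
Intermediate I is known to occur (on the order of 1000 1/s), but because the
next step (`k2`) is fast, the fit is insensitive to it.
`reversibility_sensitivity()` makes that checkable: it refits the reversible
variant at fixed `km1` values. Under rapid pre-equilibrium only
`k1·k2/(k2 + km1)` is identified, so each refit starts from the
flux-equivalent point (the `k1` start scaled by `(k2 + km1)/k2`); `k1` and
`k2` then wander along the ridge while `k3`, `km3`, `k4` stay within a few
percent of their irreversible-fit values across `km1` from 300 to
2000 1/s — which is the modelling justification for dropping `km1` from the
default scheme.

## Viscosity analysis

The degree of diffusion control of each stage is quantified by the power law
`k ~ eta^-delta`: `delta = 0` means viscosity-insensitive, `delta = 1`
diffusion-limited, `delta > 1` an enhanced effect beyond pure diffusion
control. `fit_power_law()` fits `ln k` against `ln eta` by OLS, which gives
a closed-form standard error for `delta`; the buffer (1.0 cP by convention)
is included as a point. `classify_stage()` turns the fit into a verdict
using 2-standard-error bands, checked in order: enhanced
(`delta - 2·SE > 1`), diffusion-limited (`|delta - 1| ≤ 2·SE`), insensitive
(`delta` below 0.2 or log-log slope not significant at alpha = 0.05), else
partial. The bands and the flatness test are package conventions chosen to
make the usual qualitative judgement reproducible; the precedence order
means a noisy fit straddling 1 is reported as diffusion-limited rather than
unclassifiable.

The package ships handbook viscosities for aqueous glycerol
(1.31/1.76/2.50/3.72 cP at 10–40% w/w, 20 °C) and sucrose
(1.33/1.95/3.19/6.16 cP). These are standard water-mixture table values, not
measured here; users with their own media supply a `viscosity_table()`.
With these tables, regression of the characterized flavin-binding rates
against viscosity reproduces the published exponents (about 1.60 for
glycerol against 1.62 ± 0.04; 0.95 for sucrose against 0.94 ± 0.03).

## The synthetic-data generator

`generate_curve_family()` emulates a stopped-flow acquisition campaign: it
integrates the model under a medium's preset constants for each aldehyde
concentration and applies multiplicative Gaussian noise. Defaults encode the
study conditions: post-mix 0.95 µM luciferase (1.9 µM before 1:1 mixing),
15 µM FMNH2, decanal at 10–50 µM, 0–15 s at 1 ms, and a noise model of 2%
relative SD per replicate averaged over 5 replicates — the acquisition
protocol averages at least five shots per curve, and the per-replicate noise
level is chosen so that the averaged curves support the few-percent fit
errors typical of such data. All randomness flows from the noise model's
single seed; at zero noise, generation is a pure function of (medium,
aldehydes, grid).

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: instrument dead time and mixing
artifacts in the first few milliseconds, baseline drift, detector
saturation near the peak, correlated (non-white) noise, and any model
misspecification (extra isomerization steps, aldehyde inhibition at high
concentration). Recovery results on synthetic families are therefore a
statement about estimator correctness and identifiability, not about the
adequacy of the scheme for a given instrument record.

`generate_absorbance_fixture()` similarly produces the 380-nm
Intermediate II formation decay (0–15 ms; amplitude 0.05 and baseline 0.30
are shape-plausible synthetic values) for exercising the `k2` fit.

## Degenerate inputs and errors

Traces with no interior maximum (monotone), too few points, or all-zero
signal are rejected with specific errors rather than producing nonsense
features or unidentifiable fits; a family mixing media is refused; the
exponential fit refuses non-decaying absorbance traces; metrics whose
denominators vanish (all-zero data, zero points inside the deviation
window) raise errors rather than returning infinities. The pipeline wraps
each stage and prefixes failures with the stage name (`[acquire]`,
`[features]`, `[fit]`, `[viscosity]`).

## Problem sizes used by the shipped checks

The package's own test suite and the reproduction script fit at the full
study conditions (five curves, 0–15 s at 1 ms, 8 starts) where the result is
a headline quantity, and at 10–20 ms grids with 1–4 starts for structural
and property checks, where the coarser grid changes nothing beyond the
stated tolerances. A full-condition global fit takes on the order of a
minute on one core; coarse-grid fits take a few seconds.

## Known limitations

* The oxygen dependence is folded into `k2`; the model cannot extrapolate
  across oxygen concentrations.
* `k2` estimates from luminescence alone should not be interpreted
  quantitatively (weak identifiability); use the absorbance route.
* The per-family scale convention means absolute quantum yields are only
  comparable within a family unless an external calibration is supplied.
* Power-law classification with few viscosity points (3–4) has wide
  standard errors; with only three points the `delta` SE is typically too
  large for the "enhanced" verdict ever to trigger.
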