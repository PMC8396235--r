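# luxkin

Kinetic modelling of the single-turnover bacterial bioluminescent reaction:
simulation, curve-parameter extraction, global rate-constant estimation, and
diffusion-control analysis in viscous media.

## The problem

Bacterial luciferase emits light while oxidizing reduced flavin
mononucleotide (FMNH2) and a long-chain aldehyde with molecular oxygen. In a
stopped-flow single-turnover assay each enzyme molecule turns over at most
once — free FMNH2 autoxidizes within ~0.5 s — so the record is a flash: the
intensity rises within about a second, peaks, and decays over 8–10 s. Buried
in that one curve shape are the rates of every elementary step. `luxkin` is
for enzymologists and biophysicists who want to pull those rates out of
multi-concentration curve families and ask how each step responds to medium
viscosity — the standard probe for diffusion control of enzyme mechanisms in
cytomimetic (crowded/viscous) media.

## The model

The reaction scheme, as a stiff ODE system over µM concentrations:

    E + FMNH2  --k1-->  E·FMNH2 (I1)              (flavin binding; optional reverse k-1)
    I1         --k2-->  E·FMNHOOH (I2)            (pseudo-first-order in O2-saturated assay)
    I2 + RCOH  <-k3/k-3->  E·FMNOOH·RCOH (I2A)    (aldehyde binding)
    I2A        --k4-->  excited emitter  →  light
    FMNH2      --kd-->  FMN          (dark: autoxidation)
    I2         --kdd->  FMN + H2O2   (dark: peroxyflavin decay)

The observable is the catalytic flux, `I(t) = scale · k4 · [I2A](t)`.
From each curve four empirical parameters are extracted (`Imax`, area `Q*`,
initial slope `v0`, tail rate `kdecay`). Five constants
`{k1, k2, k3, k-3, k4}` are recovered by globally fitting the model to five
curves recorded at 10–50 µM decanal with `kd`, `kdd` fixed from separate
experiments; `k2` comes independently from a monoexponential fit
`D380 = A·e^(−k2·t) + B` to the 380-nm absorbance decay. Diffusion control
of each stage is then quantified by fitting `k ~ η^−δ` across media: δ = 1
is diffusion-limited, δ > 1 an enhanced effect, δ ≈ 0 insensitive.

## Worked example

```r
library(luxkin)

## characterized buffer constants
k <- table1_presets()$buffer

## simulate one flash curve: 0.95 uM luciferase, 15 uM FMNH2, 40 uM decanal
tr <- simulate_curve(k, assay_conditions(E0 = 0.95, F0 = 15, A0 = 40),
                     t_grid = seq(0, 15, by = 0.01))
extract_features(tr)
#> Empirical curve parameters
#>   Imax   = 0.2267 a.u.      (peak intensity)
#>   Q*     = 0.7557 a.u. s    (total quantum yield, area)
#>   v0     = 1.526 a.u./s    (initial velocity, window 0-0.04 s)
#>   kdecay = 0.3358 1/s       (tail decay, window 2.53-15 s)

## generate a noisy five-concentration family and refit the constants
fam <- generate_curve_family("buffer", noise_model(sigma_rel = 0.02, seed = 42),
                             t_grid = seq(0, 15, by = 0.01))
fit_global(fam, fixed = c(kd = 7.85, kdd = 0.15),
           init = c(k1 = 1, k2 = 400, k3 = 0.5, km3 = 10, k4 = 0.5),
           options = fit_options(n_starts = 4, seed = 1))
#> Global fit [buffer]: 5 curves, objective 0.002918, converged (27 iterations, best of 4 starts)
#>   k1 = 1.555 1/(uM s), k2 = 378.1 1/s, k3 = 0.4217 1/(uM s), k-3 = 10.99 1/s, k4 = 0.4604 1/s
#>   (kd = 7.85, kdd = 0.15 1/s fixed)
#>   relative error per curve (%): 0.886, 0.867, 0.869, 0.888, 0.948; max 0.948%
#>   max pointwise deviation over 0.2-5 s: 3.49%

## the oxygen-binding step, from the 380-nm absorbance decay
fit_k2_exponential(generate_absorbance_fixture(400, noise_model(sigma_rel = 0.01, seed = 1)))
#> Monoexponential absorbance fit: k2 = 394 +/- 8.4 1/s, amp = 0.05027, offset = 0.2998

## diffusion control of flavin binding in glycerol media
vt <- default_viscosities()$glycerol
p  <- table1_presets()
pl <- fit_power_law(vt$eta, sapply(c("buffer", paste0("glycerol_", c(10, 20, 30, 40))),
                                   function(m) p[[m]]$k1))
pl
#> Power law k ~ eta^-delta: delta = 1.6 +/- 0.037 (n = 5, R2 = 0.998), prefactor = 1.58
classify_stage(pl)
#> [1] "enhanced"
```

Reading the output: the refit recovers the generating constants to within a
percent or two from 2% noise; the weakly identified `k2` lands within a few
percent of its 400 1/s start. The glycerol flavin-binding exponent δ ≈ 1.6
exceeds 1 by more than two standard errors, so that stage is classified as
showing an enhanced (beyond-diffusion) viscosity effect.

An end-to-end run — generation or file loading, features, per-medium fits,
power laws, CSV/JSON report — is `run_pipeline(run_config(...))`; a thin
command-line wrapper with `simulate` / `features` / `fit` / `k2fit` /
`viscosity` / `demo` subcommands is installed at `inst/cli/luxkin.R`.

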