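# eyedisc

Spatio-temporal modelling of *Drosophila* eye imaginal disc development:
coupled patterning and growth driven by the morphogenetic furrow.

## The problem

The adult fly eye forms from the eye imaginal disc, a sheet of
proliferating progenitor cells that is progressively converted into
differentiated retina by the morphogenetic furrow (MF) — a signalling
wave that starts at the posterior margin and sweeps anteriorly at a
constant speed. Final eye size is set by a race: progenitors ahead of
the furrow proliferate, while the furrow removes them by
differentiation. `eyedisc` is for quantitative developmental biologists
and modellers who want to simulate that race, probe how the underlying
signalling network sets the furrow's speed, reproduce classical mutant
phenotypes in silico, and estimate the kinetic parameters that feed the
model from FRAP experiments.

## The model

Five species — the morphogens Hedgehog (Hh) and Decapentaplegic (Dpp),
the Dpp-signalling readout pMad, the retinal factor Eya, and the
progenitor factor Homothorax (Hth) — obey advection–reaction–diffusion
equations on a growing 2D elliptical domain,

    dc_i/dt + div(u c_i) = D_i lap(c_i) + R_i,

with regulatory reaction terms: differentiated cells produce Hh; furrow
cells produce Dpp in proportion to local Hh; pMad tracks Dpp signalling
through a Hill function; Eya responds to pMad or Hh; and Hth production
requires the absence of both repressive inputs. Thresholds on Hth and
Hh classify tissue into progenitor (Pi), furrow (Theta) and
differentiated (Phi) states. Growth follows an incompressible
Newtonian-fluid (quasi-static Stokes) description with a proliferation
source confined to progenitors,

    div u = S = Pi * k0 * exp(-delta_PL * PL),

where PL is the furrow's posterior length. The system is irreversibly
bistable and its diffusible components turn the threshold cascade into
a travelling wave — the simulated furrow. Everything is solved with
linear finite elements on a moving (arbitrary Lagrangian–Eulerian)
mesh; measured rate constants (Hth turnover from bleach-chase FRAP, Hh
diffusion from confocal FRAP, Dpp transport, the growth-decay constant)
ship as defaults, and the package also implements the FRAP estimators
themselves. See the vignette in `vignettes/eyedisc-methods.Rmd` for the
full model, numerics and design rationale.

## Worked example

Parameter estimation from FRAP-style data, and a scaled-down disc
simulation:

```r
library(eyedisc)

half_life(6.97e-5)          # measured Hth degradation rate, s^-1
#> [1] 2.762423               # hours — the reported 2.77 h at printed precision

decay_from_length(0.033, 7) # Hh: D = 0.033 um^2/s, gradient length 7 um
#> [1] 0.0006734694           # implied clearance rate, s^-1

# bleach-chase on synthetic ground truth (delta = 1e-4 s^-1, 3% noise)
series <- gen_bleach_chase(delta_true = 1e-4, sigma = 0.03, seed = 42)
bleach_chase_decay(series)
#> bleach-chase decay estimate: delta = 0.000111 +/- 1.3e-05 s^-1 (R^2 = 0.755, n = 25)
#>   half-life 1.73 h

# confocal FRAP pipeline on a diffusion oracle with D = 0.033 um^2/s
frap <- gen_frap_recovery(D_true = 0.033, r_n = 5, K = 0.6, r_e = 6,
                          duration = 3600, frame_every = 60)
est <- estimate_frap_diffusion(frap)
round(c(D = est$D, tau_half_s = est$tau_half, r_e = est$radius$r_e), 4)
#>          D tau_half_s        r_e
#>     0.0322   236.6725     6.0000

# a small disc, 30 h of development
p <- eye_disc_parameters(a = 35, b = 25, n_rings = 10, eta = 3e-4)
run <- simulate_eye_disc(p, t_end = 30, output_every = 2)
run
#> eye_disc_sim: 15 output times over 28.2 h
#>   furrow initiation: 1.67 h; final PL 124.0 um of L_AP 124.0 um
#>   area 2744 -> 8564 um^2; 0 remesh event(s)

sel <- run$time >= 8 & run$PL > 0 & run$PL < 0.93 * run$L_AP
fit_mf_kinetics(run$time[sel], run$PL[sel])
#> furrow kinetics: speed 4.2 um/h, RMSE 0.948 um (n = 7, window 8.1-20.1 h)
```

The numbers read as follows: the half-life and clearance-rate helpers
reproduce the measured worked values; the bleach-chase estimator
recovers the true 1e-4 s^-1 within its reported uncertainty; the FRAP
pipeline recovers D = 0.033 within 3%; and on the small disc the furrow
initiates at ~1.7 h, traverses the disc linearly (RMSE under 1 um) and
differentiates the whole epithelium, tripling the disc area on the way.
At the full wild-type defaults (`eye_disc_parameters()`, 75 h) the
furrow moves at ~3.5 um/h, close to the measured 3.4 um/h, and growth
terminates when the progenitor pool is exhausted.

Mutant experiments are one argument away, e.g. a Hh hypomorph
`simulate_eye_disc(p, perturbations = perturbation("p_Hh", "scale", 0.85))`
slows and halts the furrow while the disc overgrows; clones are
perturbations with a `region`. `sensitivity_sweep()` reruns the model
with ±1% parameter changes, `scaling_test()` analyses anterior Dpp/pMad
gradient scaling, and `calibrate()` fits free parameters against
furrow-relative expression profiles.

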