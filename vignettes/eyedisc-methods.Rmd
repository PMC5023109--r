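---
title: "Modelling eye disc patterning and growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling eye disc patterning and growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eyedisc)
```

# The model

During the third larval instar, the *Drosophila* eye imaginal disc is
patterned by the morphogenetic furrow (MF), a differentiation wave that
sweeps from the posterior margin to the anterior pole. Ahead of the
furrow, progenitor cells expressing the transcription factor Homothorax
(Hth) proliferate; behind it, cells differentiate into retina and
express Hedgehog (Hh). `eyedisc` implements a parsimonious
reaction–transport model of this process on a growing two-dimensional
elliptical domain.

Five species are tracked as continuum concentration fields: the
diffusible morphogens Hh and Dpp, the intracellular Dpp-signalling
readout pMad, the retinal determination factor Eya, and Hth. Each obeys
an advection–reaction–diffusion equation in conservation form,

$$\partial_t c_i + \nabla\cdot(u\,c_i) = D_i \nabla^2 c_i + R_i,$$

where $u$ is the tissue velocity generated by growth. The reaction
terms encode the regulatory logic:

$$
\begin{aligned}
R_{Hh} &= p_{Hh}\,\Phi - \delta_{Hh} c_{Hh}\\
R_{Dpp} &= p_{Dpp}\, c_{Hh}\,\Theta - \delta_{Dpp} c_{Dpp}\\
R_{pMad} &= p_{pMad}\,\sigma_{Dpp} - \delta_{pMad} c_{pMad}\\
R_{Eya} &= p_{Eya}(\sigma_{pMad} + \sigma_{Hh}) - \delta_{Eya} c_{Eya}\\
R_{Hth} &= p_{Hth}\,\bar\sigma_{pMad}\,\bar\sigma_{Hh} - \delta_{Hth} c_{Hth}
\end{aligned}
$$

with Hill activation $\sigma_i = c_i^{n_i}/(c_i^{n_i}+K_i^{n_i})$ and
repression $\bar\sigma_i = 1-\sigma_i$. Cell states are indicator
fields defined by Heaviside thresholds: progenitors
$\Pi = H(c_{Hth}-\theta_{Hth})$, furrow cells
$\Theta = (1-H(c_{Hth}-\theta_{Hth}))(1-H(c_{Hh}-\theta_{Hh}))$, and
differentiated cells
$\Phi = (1-H(c_{Hth}-\theta_{Hth}))H(c_{Hh}-\theta_{Hh})$; they always
form a partition of unity. Hh enters through a flux boundary condition
on the posterior 20% of the margin, active until 10 h and then shut
down on a ramp of slope $1/(1\,\mathrm{h})$ that is cut at 10.5 h (so
the influx drops from half strength straight to zero — the form the
source formula takes when transcribed literally; the discontinuity is
dynamically irrelevant because margin influx is by then dwarfed by Hh
made in the differentiated territory).

Tissue mechanics follow the incompressible-Newtonian-fluid picture with
a proliferation source restricted to progenitors,

$$\nabla\cdot u = S = \Pi\, k_0\, e^{-\delta_{PL}\, PL},$$

where $PL$, the posterior length, is the distance from the posterior
pole to the furrow at the dorsoventral midline. At tissue scales the
Reynolds number is negligible, so the package solves the quasi-static
Stokes limit of the momentum equation with zero-traction boundaries
(the printed momentum balance carries inertial terms; dropping them
changes nothing at µm/h velocities, and removes stiff dynamics). For a
spatially uniform source the zero-traction Stokes solution is an exact
isotropic dilation — the model's growth-rule anisotropy
$\epsilon = \partial_y u_y / \partial_x u_x$ is exactly 1 — and this is
how the packaged anisotropy diagnostic should be read: it equals 1
while progenitors fill the disc and drifts once the non-growing
posterior territory reaches the centroid neighbourhood.

## Travelling-wave structure (why the parameters sit where they do)

The system is irreversibly bistable and Hh and Dpp diffuse, so the
threshold cascade propagates as a travelling wave. Two wave modes
coexist. In a *band-free* mode, Hh repression alone drives the Hth
crossing and cells differentiate the moment they leave the progenitor
state; no Θ band and hence no Dpp is produced. In the *banded* mode the
Dpp→pMad arm pushes the Hth front ahead of the Hh differentiation
contour, a Θ stripe of finite width appears, and the furrow speed is
paced by the advance of the differentiation edge, approximately

$$v \;\approx\; \sqrt{4 D_{Hh}\delta_{Hh}}\;
\frac{1-2\hat\theta}{2\sqrt{\hat\theta(1-\hat\theta)}},
\qquad \hat\theta = \frac{\theta_{Hh}\,\delta_{Hh}}{p_{Hh}},$$

because the Hh level at the edge of a half-plane source is half the
interior plateau. This expression explains three headline behaviours at
once: the strong sensitivity of furrow speed to the Hh parameters, the
halt of the furrow when Hh production is reduced (the wave stalls as
$\hat\theta \to 1/2$), and the collapse of differentiation altogether
when the margin influx is removed. The packaged wild type sits in the
banded regime at $\hat\theta \approx 0.42$.

# Parameters

Units are seconds and micrometres; concentrations are arbitrary.
Measured quantities ship verbatim as defaults:

| quantity | value | origin |
|---|---|---|
| $\delta_{Hth}$ | $6.97\times10^{-5}\,\mathrm{s^{-1}}$ | bleach-chase FRAP (half-life 2.77 h) |
| $D_{Hh}$ | $0.033\,\mathrm{\mu m^2 s^{-1}}$ | confocal FRAP |
| $\delta_{Hh}$ | $6.7\times10^{-4}\,\mathrm{s^{-1}}$ | $D_{Hh}/\lambda^2$ with the 7 µm Hh gradient length |
| $D_{Dpp}$, $\delta_{Dpp}$ | $0.1$, $2.5\times10^{-4}$ | wing disc effective transport |
| $D$ (pMad, Eya, Hth) | $2.5\times10^{-4}$ | small effective intracellular diffusion, kept nonzero for numerical stability |
| $\delta_{PL}$ | $0.0107\,\mathrm{\mu m^{-1}}$ | exponential decline of the area growth rate with posterior length |

Absolute concentrations are unobservable, so all production rates are
set equal, $p_i = \delta_{Hth}$, which normalises the progenitor Hth
steady state to 1 and makes thresholds readable as fractions of maximal
Hth. The remaining constants (Hill parameters, thresholds, influx
amplitude $\eta$, initial growth rate $k_0$, initial semi-axes) are not
fixed by measurements; the packaged values were obtained by calibrating
the full growing-domain model against the furrow speed (3.4 µm/h), the
linearity of furrow movement, growth termination, the rise-then-fall of
the anterior length with closely matched values at 20 h and 40 h, and
qualitative furrow-relative profile shapes (pMad peaked at the furrow,
Hth rising anteriorly, Eya high posteriorly). Two calibration choices
deserve emphasis:

* **Band selection.** The Hill constants were chosen so that the
  Dpp→pMad arm sustains the Θ band ($K_{Dpp}$ at the Dpp amplitude
  scale, $K_{pMad}$ below the pMad plateau, $K_{Hh}$ well below
  $\theta_{Hh}$). Weakening this arm collapses the model into the
  band-free wave, in which Dpp-dependent behaviour disappears entirely.
* **Discretisation-aware thresholds.** The effective propagation
  threshold of the differentiation edge includes front-curvature and
  mesh-resolution corrections (the Hh gradient length, 7 µm, is only
  twice the element size). $\theta_{Hh}$ was therefore calibrated on
  the production discretisation, not on an idealised fine-grid limit;
  general-purpose FEM solvers are routinely applied to this system at
  comparable (≈5 µm) element sizes, so the calibration absorbs the
  discretisation the same way.

`eye_disc_parameters()` builds the validated set; every value can be
overridden by name, or loaded from a flat YAML file with
`read_parameters()`.

# Numerics

**Discretisation.** Linear (P1) finite elements on a structured
triangulation of the ellipse (concentric rings, $6m^2$ elements for
$m$ rings; the default $m = 12$ gives a ~3.5 µm edge length). The
velocity solve uses equal-order P1–P1 elements with Brezzi–Pitkäranta
pressure stabilisation; the rigid-body nullspace of the all-traction
problem is removed by pinning point degrees of freedom, which is exact
here because the compatible source exerts no net force or torque.

**Time stepping.** Operator splitting with a 250 s step cap: classify
cells, compute the growth source and (every few steps; the source
changes on the hour scale) the Stokes velocity, move mesh nodes with
the flow, then update all species. Because nodes travel with the
material, advection and growth dilution are carried exactly by the
change of the finite-element mass matrix,
$M^{n+1} c^{n+1} = M^n c^n + \ldots$, which conserves total mass to
round-off in the absence of reactions and boundary flux. Linear decay
is applied by its exact exponential factor, production explicitly with
the matched effective duration $(1-e^{-\delta\,\mathrm{d}t})/\delta$,
and diffusion implicitly. One consequence worth knowing: growth dilutes
Hth, so the progenitor level during fast growth sits at
$p/(\delta+S)$, below the static steady state — this is the model's own
transport equation at work, not an artefact.

**Heaviside regularisation.** Sharp steps are used for classification
and reporting; the PDE right-hand sides use a tanh-smoothed step of
width 1% of the respective threshold.

**Remeshing.** A remesh triggers when the minimum element quality
(scaled inradius/circumradius) falls below 0.3 or when the median
element has grown 1.4-fold beyond the target size. The new mesh
resamples the current boundary uniformly by arc length, scales ring
copies toward the centroid, transfers fields by linear interpolation
(exact for affine fields, mass-conserving to well under 1% per event),
and keeps the *element size* — not the element count — constant as the
disc grows. Without the size-preserving policy the stretching anterior
under-resolves the Hh gradient and the front stalls numerically. If a
candidate remesh would be worse than the current mesh it is skipped.

**Furrow tracking.** $PL$ is read in a two-element-layer band around
the DV midline from the bin-averaged Hth profile, interpolating the
$\theta_{Hth}$ crossing linearly; this makes $PL$ continuous under
parameter changes, which the ±1% sensitivity sweep depends on.

**Problem sizes.** The packaged wild-type run uses the 12-ring mesh
(864 elements initially, growing to a few thousand as the disc
expands), 250 s steps over 75 h, velocity refresh every 6 steps;
perturbation studies use a scaled-down 35 × 25 µm disc with a raised
influx amplitude ($\eta = 3\times10^{-4}$, above the initiation
threshold so that influx titrations still initiate). The 1D oracle
solves 5 × 400 stiff ODEs by method of lines.

# FRAP estimation

**Bleach-chase.** After partial photobleaching, the difference between
unbleached and bleached region intensities decays as
$d(t) = d(0)e^{-\delta t}$ regardless of production; `bleach_chase_decay()`
fits $\log d$ against time by OLS and reports $\delta$, its standard
error, $R^2$ and the half-life $\ln 2/\delta$. Points with non-positive
differences are dropped with a warning. On the documented acquisition
(120 min, one frame per 5 min) the Hth rate spans only ~0.4 half-lives,
so single-movie estimates are intrinsically noisy; the generator-based
tests quantify exactly how noisy.

**Confocal FRAP.** The diffusion coefficient follows the simplified
formula $D = (r_e^2+r_n^2)/(8\tau_{1/2})$. The effective radius $r_e$
is estimated from the postbleach profile by two routes: a nonlinear
least-squares Gaussian fit, and a fit-free reading of the half-width at
0.86 of the bleach depth. These two are mutually consistent only under
the factor-2 Gaussian convention
$f(x) = 1 - K e^{-2x^2/r_e^2}$, which is therefore the default: under
the plain convention ($e^{-x^2/r_e^2}$, selectable as
`convention = "plain"`) the same $D$ formula systematically
under-recovers diffusion coefficients by ~40% on synthetic
ground-truth data, while the factor-2 convention recovers them within
~15%. The half-recovery time uses the plateau (mean of the final 10% of
frames) and linear interpolation between the bracketing frames.

# Synthetic data

All estimator tests run against generators with known ground truth:
exponential-difference bleach-chase pairs with multiplicative
log-normal (or additive Gaussian) noise; a finite-difference 2D
diffusion oracle that evolves a Gaussian bleach spot and records the
ROI recovery curve and postbleach profile — a numerical route entirely
independent of the estimators; parametric furrow-relative expression
profiles with the qualitative shapes of the measured gradients; and a
1D method-of-lines front solver sharing the reaction terms (but not the
transport discretisation) with the 2D engine, used as a cross-check of
the front speed on a static domain (they agree within ~4%).

What the generators deliberately do not emulate: microscope imaging
artefacts (bleaching during acquisition, drift, segmentation error),
cell-scale granularity, or biological replicate variability beyond the
stated noise models. Passing tests therefore validate the estimation
machinery and the model's internal consistency, not the biological
accuracy of any particular measured number.

# Analysis choices

* *Furrow kinetics*: OLS slope of $PL(t)$; nonlinearity = RMSE of the
  residuals. The headline speed is fitted from furrow initiation until
  the furrow nears the pole (93% of the AP length).
* *Final area* for sensitivity readouts: total area at growth
  termination, defined as relative area growth dropping below 1%/h.
* *Decay lengths*: profiles are band-averaged along the midline; the
  anterior decay length is fitted in log space with the
  reflected-boundary model $A\cosh((L-x)/\lambda)$, because the
  zero-flux anterior pole flattens the tail and a plain exponential fit
  inflates $\lambda$ once the anterior is only a few $\lambda$ long
  (late development). With a long anterior the two fits coincide.
* *Calibration*: free parameters are fitted in log space (Nelder–Mead)
  against unit-max-normalised furrow-relative profiles, with an
  optional furrow-speed penalty, using the 1D solver for speed; the
  result never degrades the starting residual.

# Known limitations

* No cell death or survival signalling: hypomorphic conditions
  overgrow, as the model structure predicts they must.
* Cell-state classification is memoryless: if Hh collapses,
  "differentiated" tissue can revert. Strong Hh hypomorphs
  (production below ~0.8 of wild type) therefore unravel rather than
  merely stall; the packaged hypomorph study uses 0.85, which stalls
  with a persistent retina.
* The furrow-speed landscape is steep near the propagation threshold
  (by the $v(\hat\theta)$ relation above), so moderate parameter
  changes can flip the system between banded, band-free, stalled and
  runaway-growth regimes. This mirrors the strong ±1% sensitivities of
  the original study, but it means custom parameter explorations should
  watch the band (Θ area) and the area trajectory.
* Dorsoventral biology (Wg signalling), receptor dynamics (Ptc) and
  gradient-scaling mechanisms are out of scope; indeed the model's
  anterior Dpp gradient keeps a constant decay length, so the apparent
  late-time "expansion" after normalisation is purely a consequence of
  the shrinking anterior — the model cannot explain measured gradient
  scaling, and does not try to.
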