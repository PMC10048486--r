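---
title: "Image-analysis microrheology of gelation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-analysis microrheology of gelation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelscope)
```

## The problem

When milk is acidified (for instance with glucono-delta-lactone, the
acidulant used to mimic bacterial fermentation in fresh cheese and yogurt),
the casein micelles lose charge, aggregate near their isoelectric point and
percolate into a space-spanning gel.  The micron-sized fat globules
suspended in the milk take no part in the chemistry, but their Brownian
jitter is throttled by the stiffening matrix: they are free passive probes
of the sol-gel transition.  gelscope turns time-lapse bright-field movies
of those probes into quantitative gelation observables through three
complementary analyses, and pairs them with classical loss-tangent
rheology:

* **PIV** (particle image velocimetry): block-matching displacement fields
  between frames separated by a fixed lag; their mean magnitude, tracked
  across a gelation run and normalized to the first movie, is the
  *mobility curve* whose sudden decay marks dynamical arrest.
* **DVA** (differential variance analysis): the pixel variance of frame
  differences $\Delta I = I(t+\Delta t) - I(t)$ grows with lag and
  saturates at a plateau $I_\infty$ once the probe configuration has
  decorrelated.  The dynamic order parameter
  $Q(\Delta t) = 1 - \langle I(\Delta t)\rangle_t / I_\infty$
  decays from 1 to 0 and is fitted with a stretched exponential
  $\exp[-(\Delta t/\tau)^\beta]$.
* **DDM** (differential dynamic microscopy): the azimuthally averaged
  power spectrum of frame differences, the image structure function
  $D(q,\Delta t) = A(q)\,[1 - f(q,\Delta t)] + B$, gives the intermediate
  scattering function $f(q,\Delta t)$ at any wavevector — a light-scattering
  experiment performed with a microscope.  For Brownian probes
  $f = \exp(-D_t q^2 \Delta t)$, and the probe mean-square displacement
  follows from $f$ without tracking a single particle.
* **Rheology utilities**: $\tan\delta = G''/G'$; the Winter–Chambon gel
  point as the time at which $\tan\delta$ becomes frequency-independent
  (near 1); power-law aging exponents of $G'$, $G''$ and $\tan\delta$
  after the post-gel modulus maximum.

Because no laboratory movie ships with the package, a synthetic-data module
generates everything with known ground truth: trajectory ensembles
(Brownian, fractional Brownian, harmonically trapped), rendered movies, and
three-stage rheology traces.  Every analysis stage is validated against
those ground truths in the test suite.

## The synthetic generator

`simulate_trajectories()` draws independent 2-D paths:

* *brownian*: increments $\mathcal N(0,\,2D\,\mathrm dt)$ per axis; 2-D MSD
  $= 4D\Delta t$.
* *fbm*: fractional Gaussian noise with Hurst exponent $H$, synthesized
  exactly from its covariance (Cholesky factorization up to 2048 steps,
  Davies–Harte circulant embedding beyond); 2-D MSD $= 4D\Delta t^{2H}$.
  Sub-diffusion with Gaussian increments is the standard minimal model for
  probes embedded in a viscoelastic network.
* *trapped*: an exactly discretized Ornstein–Uhlenbeck position process
  (overdamped harmonic well, stiffness $k$, noise intensity $c$); the MSD
  saturates at $4c/k$.  This represents deep arrest — a probe caged by the
  casein network.  The confinement mechanism in a real gel is not known in
  microscopic detail; the harmonic cage is the simplest model with the
  observed MSD plateau.

Unwrapped coordinates are kept for ground-truth MSDs; the renderer wraps
positions periodically into the field of view.  `render_movie()` draws each
probe as an analytic 2-D Gaussian spot (evaluated at sub-pixel position over
a 6-sigma window — tighter truncation leaves step edges whose spurious
high-wavevector power contaminates the DDM noise floor), sums spots and
background, optionally applies Poisson shot noise, adds Gaussian read noise,
and quantizes to 8 or 16 bits with clipped pixels counted in a render
report.  When the trajectory box coincides with the field of view, spots
wrap periodically at the edges for the same spectral-hygiene reason.

Default movie geometry is 256 x 256 px at 0.1 um/px, 500 frames at 50 Hz
(a 10 s movie), with 0.57 um-radius probes — the imaging regime of the
acid-milk experiments this package emulates.  Smaller geometries are used
in parts of the test suite and in the default pipeline configuration purely
to keep example runs quick; they are stated where used.

### Key default parameters

| parameter | default | units | why |
|---|---|---|---|
| `probe_radius` | 0.57 | um | mean fat-globule radius of the emulated system |
| `temperature` | 298.15 | K | the experiments run at 25 C |
| frame rate | 50 | Hz | emulated camera |
| `pixel_size` | 0.1 | um/px | emulated optics |
| `psf_sigma` | 0.7 | px | see below |
| `peak_intensity` / `background` / `read_noise_sigma` | 300 / 100 / 3 | counts | mid-range 16-bit contrast, realistic SNR |
| gel-state preset | $H = 1/6$, $D = 0.04$ | —, um^2/s^(1/3) | see below |
| rheology `tc` | 32 | min | canonical crossover time of the emulated run |
| aging exponents | −0.23 / −0.38 | — | canonical storage/loss aging slopes |

**Why psf_sigma = 0.7 px.**  For Gaussian spots of width $\sigma$ the DVA
order parameter of Brownian probes is analytically a band-integrated
mixture, $Q(\Delta t) = (1 + D\Delta t/\sigma^2)^{-1}$, whose effective
relaxation time is $\approx 1.7\,\sigma^2/D$.  The DDM relaxation time at
the probe wavevector $q_R = 2\pi/R$ is $1/(D q_R^2)$.  The two probe the
*same* dynamics only when the image passband is centred on the probe
wavevector, i.e. $\sigma \approx 0.77/q_R \approx 0.07$ um.  At the default
pixel size that is 0.7 px — a tight, slightly undersampled spot, appropriate
for a weakly contrasted micron globule imaged near the diffraction limit.
With this choice the DVA-vs-DDM relaxation-time comparison at $q_R$ is
meaningful (and holds within 25% in the test suite).

**Why the gel-state preset has $D = 0.04$.**  $H = 1/6$ gives the MSD
log-log slope $1/3$ of strongly subdiffusive arrested-gel probes.  The
amplitude is fixed so that the probe-scale ISF decays essentially to zero
within a 10 s movie ($f(2.5\,\mathrm s) \approx 10^{-3}$): the structure
function's amplitude $A(q)$ can only be read off a *converged* long-lag
plateau, and a slower preset would make the gel state unanalyzable at this
movie length — the same long-lag ensemble limitation that forces real
late-stage curves to be discarded.

**Rheology construction.**  `synthesize_rheology()` builds
$\tan\delta(t,\omega) = \exp[\psi(t)\,h(\omega)]$ with $\psi(t_c) = 0$, so
the loss-tangent curves of *all* frequencies intersect exactly at $t_c$
with common value 1 — the Winter–Chambon signature holds by construction,
not approximately.  $G'$ is flat in the sol, rises smoothly (a smoothstep
in log-modulus) to its maximum at $t_{peak}$, and then decays as
$t^{a}$; in the aging stage $\tan\delta \propto t^{\,b-a}$, so
$G'' = G'\tan\delta \propto t^{b}$ exactly.  Noise, when requested, is
multiplicative log-normal with the given coefficient of variation.

## Numerical choices

* **Lag grids** default to 20 log-spaced integer-frame lags from one frame
  interval to a quarter of the movie duration; the cap keeps at least ~375
  frame pairs per lag at 50 Hz / 10 s.  DVA averages over *all* overlapping
  start frames (the long-lag artifact is an ensemble-size problem, so pairs
  are maximized and `n_pairs` is reported); DDM caps pairs at 100 evenly
  spaced start frames by default for tractability, with frame FFTs computed
  once and differenced in Fourier space.
* **Plateau acceptance** (DVA plateau and per-q DDM amplitude): the mean
  over the top half-decade of lags is accepted only if the local log-log
  slope there is below 0.05 per decade; otherwise the quantity is declared
  not estimable, with the residual slope in the error.  Nothing is silently
  extrapolated.
* **Noise floor $B$**: a single scalar, the median of $D(q,\Delta t_{min})$
  over the top 10% of wavevectors.  This assumes the optics are
  band-limited at the Nyquist wavevector; with the deliberately tight
  default spot the estimate is biased high by residual signal, but the bias
  is two orders of magnitude below $A(q_R)$ and shifts the probe-scale ISF
  by about 2%, which propagates to roughly 0.02 on the MSD exponent.
* **MSD extraction**: lags are retained while $f$ lies inside
  (0.005, 0.98) and the curve is truncated at its first crossing below the
  floor — once the signal has decorrelated, later $f$ values are noise
  about zero and a positive fluctuation must not re-enter the fit.  The
  log-log slope is weighted least squares with weights $(f\ln f)^2$, the
  inverse-variance weighting of $\log$ MSD under near-constant noise on
  $f$; both the barely-decayed and the nearly-decorrelated ends of the
  curve then carry vanishing weight, which makes the estimate robust
  without a hard fit-window heuristic.  When the lag grid deliberately
  contains long plateau-anchor lags (their only job is to pin $A(q)$),
  `max_lag` excludes them from the slope fit.
* **Stretched-exponential fits** use bounded Levenberg–Marquardt with a
  deterministic multi-start (decade grid of $\tau$ across the lag range
  $\times$ $\beta \in \{0.5, 1, 1.5\}$); $\beta$ is bounded to [0.2, 2]
  (below 0.2 the fit is degenerate on a 10 s movie; above 2 is
  compressed-exponential territory this package does not model).  A $\tau$
  on the search boundary raises a warning flag.
* **PIV** uses zero-normalised cross-correlation (FFT correlation plus
  integral-image local statistics), 32 px blocks with 50% overlap inset by
  the search radius, three-point parabolic sub-pixel refinement per axis,
  and a 0.3 correlation-peak validity threshold (textureless blocks
  otherwise emit noise vectors).  Sub-pixel resolution is about 0.1 px.
* **Changepoint**: a continuous two-segment piecewise-linear (hinge) fit,
  scanned over interior sample positions and refined continuously — chosen
  over CUSUM-style methods because mobility curves have of order ten
  points.  A curve already explained by one line yields a degenerate-knee
  flag instead of an arbitrary time.  Note the knee of a hinge model marks
  the *onset* of the abrupt decay; on a schedule whose arrest is
  instantaneous (one stage free, the next fully frozen, then flat) the
  model is mis-specified and the knee drifts to the end of the cliff, so
  end-to-end consistency is exercised on a progressive-arrest schedule.
* **Winter–Chambon detection** minimizes the coefficient of variation of
  $\tan\delta$ across frequencies over time, refining the minimum by a
  parabola through its three neighbours *only when the minimum is strictly
  positive* — an exact zero on the grid (the noise-free synthetic
  crossover) is returned untouched, because the parabola through an
  asymmetric V overshoots.  A minimum that stays above half the median
  dispersion raises a shallow-minimum (no-gel) flag.

## Two deliberate interpretation choices

**The MSD inversion uses the Gaussian form by default.**  The general
inversion $\langle r^2\rangle = (4/q^2)(-\ln f)^{1/\beta}$ contains a
subtlety: if $\beta$ is taken from the stretched-exponential fit of the
*same* curve, the exponent $1/\beta$ exactly linearises any Gaussian
sub-diffusion ($-\ln f \propto \Delta t^{2H}$ fits $\beta = 2H$, and
$(-\ln f)^{1/\beta} \propto \Delta t$ always), so sub-diffusive MSD slopes
could never be observed through that route.  For probes with Gaussian
displacement statistics at every lag — Brownian motion and fractional
Brownian motion alike — the exact relation is
$f = \exp(-q^2 \langle r^2\rangle / 4)$, i.e. the inversion with
$\beta = 1$.  `isf_to_msd()` therefore defaults to `beta = 1`, which
recovers slope 1 for free diffusion and slope $2H$ for fbm; passing the
fitted $\beta$ instead applies the strict stretched-Brownian model
inversion, which is only meaningful when $\beta < 1$ reflects genuinely
non-Gaussian dynamics rather than sub-diffusion.

**Two relaxation-time conventions coexist and are not forced to agree in
absolute terms.**  The microscopic viscosity uses the probe-size
diffusion time $\tau = 6\pi\eta R^3/(k_B T) = R^2/D$ verbatim
(`microscopic_viscosity()` is its exact algebraic inverse, and doubling
$\tau$ exactly doubles $\eta_\tau$).  A relaxation time read off an ISF
decay at $q_R = 2\pi/R$, however, is $1/(D q_R^2) = (R^2/D)/(2\pi)^2$ —
shorter by the fixed factor $(2\pi)^2 \approx 39.5$.  Both conventions are
legitimate; what is physical is *relative* evolution: $\tau$ from either
route grows linearly with medium viscosity (tested within 10%), the two
imaging routes agree with each other at $q_R$ (tested within 25%), and
$\eta_\tau(t)/\eta_\tau(0)$ tracks gelation regardless of the convention.
Absolute $\eta_\tau$ values inherit the convention factor of whichever
$\tau$ is supplied, and the package reports both routes rather than hiding
a conversion constant inside one of them.

## What the generator does and does not emulate

The synthetic movies reproduce: probe-scale dynamics (free, sub-diffusive
and arrested), shot/read noise and quantization, sub-pixel spot rendering,
the frequency-collapse gel-point signature, and post-gel power-law aging.
Passing tests therefore demonstrate that the *analysis chain* recovers
known dynamics from realistic imagery.

They do not demonstrate robustness to what the generator omits:

* **Spot spectra.**  Real bright-field globule images have edged, ringed
  spots with broad power spectra; Gaussian spots concentrate power near
  one band.  One visible consequence: the DVA order parameter of a
  Brownian *synthetic* movie is analytically Lorentzian in time and fits a
  stretched exponential with $\beta \approx 0.5$–0.8, whereas experimental
  DVA curves can look single-exponential.  The DVA stage is validated by
  exact algebraic round-trips and by its relaxation time (which is
  accurate); $\beta$ from synthetic DVA curves characterizes the renderer
  as much as the dynamics.
* **Hydrodynamic and steric interactions** between probes, and between
  probes and the network; probes are independent.
* **3-D motion and defocus** — trajectories are planar and spots never blur.
* **The matrix itself** — the casein network is not rendered, and pH
  kinetics are not modelled (an externally supplied pH-threshold time can
  be attached to reports via `gel_point_external()`).
* **Heterogeneity** — no spatial gradients of gelation within a movie and,
  by default, no probe polydispersity (a Gaussian radius spread of
  0.027 um can be enabled in a schedule to mirror the emulated system's
  measured spread, but analyses use the mean radius regardless).
* **Post-gel frequency dependence of $\tan\delta$** away from the
  crossover is reproduced only in its collapse at $t_c$ and aging
  power law; the detailed high-frequency shape of a real aging gel is not
  parameterized.

## Problem sizes

The canonical analysis conditions are 500 probes, 500 frames at 50 Hz,
256 x 256 px — the full emulated imaging regime, used for the headline
MSD-exponent checks and by `scripts/acceptance.R`.  Module-level tests use
smaller ensembles (typically 150–400 probes, 96–256 px, 150–500 frames),
chosen so that each statistical tolerance is met with comfortable margin by
the statistics of the fixture itself; every tolerance in the test suite was
set from the closed-form expectation or an independent oracle, not from an
observed run.

## A compact end-to-end example

```{r pipeline, eval = FALSE}
cfg <- default_pipeline_config(seed = 1)
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
plot(report$mobility)
```

The report table carries, per elapsed time: the normalized PIV mobility,
DVA and DDM relaxation times and stretch exponents, microscopic viscosities
from both routes, and the DDM MSD exponent; globally it carries the
PIV-changepoint arrest time and (when rheology is enabled) the
Winter–Chambon gel point and the three aging exponents.  Stages whose
relaxation does not complete within the movie appear as NA with the
diagnostic preserved — the package's rendering of the fact that late-stage
experimental curves also stop being analyzable when long-lag ensemble
averaging runs out.

## Known limitations

* DVA and DDM assume statistically stationary dynamics *within* one movie;
  a movie straddling the gel point mixes states.
* The $B$ estimator needs either band-limited optics or a noise floor well
  below the signal; with very dim probes, estimate $B$ from a static
  reference movie instead.
* The hinge changepoint needs at least one sampled point inside the decay;
  single-step collapses snap to the nearest stage.
* Reported microscopic viscosities are convention-bound (see above);
  compare them across time, not against a viscometer reading, unless the
  $\tau$ convention is matched first.
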