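---
title: "Methods: coupled population-service dynamics and emergent urban length scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled population-service dynamics and emergent urban length scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(urbanpattern)
library(ggplot2)
```

## The model

`urbanpattern` simulates and analyses a pair of coupled integro-differential
equations for residential population density $p(x,t)$ (persons km$^{-2}$)
and service land fraction $s(x,t) \in [0,1]$ on a periodic domain. Both
species benefit from proximity to the other, with "how near is near"
encapsulated in normalized Gaussian spatial weight kernels
$G(x,\beta)$ of length scale $\beta$ km.

**Attractiveness.** A location attracts residents if services are available
nearby but the location itself still has room to live:
$$A = (w_{p1} * s)\,(1 - s),$$
where $*$ is spatial convolution. By default $w_{p1} = G(\cdot, \beta_{p1})$
with $\beta_{p1} = 1$ km (walking distance). When a preferred distance
$a_p > 0$ to services is switched on (competition and growth variants),
$w_{p1}$ becomes the symmetric shifted pair
$\tfrac12\{G(x + a_p, \beta_{p1}) + G(x - a_p, \beta_{p1})\}$: people want
services close, but not on their doorstep.

**Movement.** Residents relocate from $y$ to $x$ at a rate proportional to
the attractiveness of the destination, the population at the origin, and a
kernel $w_{p2} = G(\cdot, \beta_{p2})$, $\beta_{p2} = 10$ km, of the distance
moved:
$$\partial_t p = D \int \left[A(x)\,p(y) - A(y)\,p(x)\right]
  w_{p2}(x - y)\, dy
  = D\left[A\,(w_{p2} * p) - p\,(w_{p2} * A)\right].$$
The exchange is antisymmetric, so movement conserves total population
exactly; this is the base variant's only population dynamic.

**Services.** Service provision relaxes towards a carrying capacity set by
the surrounding population $P = w_s * p$ ($\beta_s = 5$ km, the typical trip
to shops):
$$\partial_t s = (f + g s)\,\left(\sigma(P) - s\right), \qquad
  \sigma(P) = 1 - e^{-(P/\lambda)^\mu}.$$
$f = 0.05$ yr$^{-1}$ is the rate of *innovators* (new businesses where
demand exceeds supply), $g = 2$ yr$^{-1}$ the rate of *imitators*
(expansion of existing ones). $\sigma$ is sigmoidal for $\mu > 1$: at low
population the fixed costs of a business barely pay off, then a tipping
point steepens the response. $\lambda = 20\,000$ persons km$^{-2}$ and
$\mu = 3$ are calibrated against London ward densities; inverting the
homogeneous relation $s = \sigma(p)$ at a ward mean of 8 400 persons
km$^{-2}$ and non-domestic land fraction 0.06 gives $\mu \approx 3.2$, and
the package recomputes that inversion as a self-check.

**Competition variant.** Residents take space from services: the drive
becomes $x = \sigma(P) - (s + \alpha_1 p)$ with
$\alpha_1 = 1.5\times10^{-5}$ km$^2$ person$^{-1}$, and innovation is gated
by a Heaviside factor $H(x)$ so that $s = 0$ is an invariant lower bound:
$$\partial_t s = \left(H(x)\,f + g s\right) x.$$
We fix $H(x) = 1$ iff $x > 0$; at exact supply-demand balance the choice
multiplies a zero and does not affect trajectories, but a fixed convention
keeps runs deterministic.

**Growth variant.** Logistic population growth with service crowding is
added to the movement equation:
$r\,p\,(1 - (p + \alpha_2 s)/c)$ with $r = 0.05$ yr$^{-1}$,
$c = 12\,000$ persons km$^{-2}$, $\alpha_2 = 10^5$ persons km$^{-2}$.

All units are km, years, persons km$^{-2}$; $s$ is a pure fraction.

## Spectral representation and boundary conditions

All kernels have analytic Fourier transforms
($\hat G(k) = e^{-\beta^2 k^2/2}$; the shifted pair multiplies this by
$\cos(a_p k)$), so convolution is evaluated spectrally: FFT the field,
multiply by $\hat w$ at the grid's discrete angular wavenumbers, transform
back. This avoids truncation artifacts entirely, at the price of requiring
the domain to be large relative to the kernel (we enforce
extent $\ge 10(\beta + a_p)$, keeping the periodic-image error below
$10^{-6}$ of the kernel mass).

Boundary conditions are periodic everywhere. This is the natural setting
for the Fourier-mode stability analysis and for cosine initial data; it also
makes the convolution exact. In two dimensions the kernels are isotropic and
$\hat w(|k|)$ is applied radially; for the shifted pair this spectral form
*defines* the 2-D kernel (its physical profile is recovered numerically as
an inverse Hankel transform in `kernel_profile()`), which keeps the 1-D
analysis and the 2-D simulations consistent.

Wavenumbers are angular (rad km$^{-1}$), so wavelength $= 2\pi/k$; a
dominant mode at $k \approx 0.14$ corresponds to $\approx 45$ km between
cities.

## Linear stability and emergent length scales

A homogeneous state $(p_0, s_0)$ exists for every mean population
$\bar p$ (base: $s_0 = \sigma(p_0)$; competition:
$s_0 = \max(0, \sigma(p_0) - \alpha_1 p_0)$, with services extinct below
the threshold where $\sigma(p) = \alpha_1 p$, about 11 500 persons
km$^{-2}$ at defaults; growth: $p_0 + \alpha_2 s_0 = c$ solved by bracketed
bisection). Sinusoidal perturbations $e^{ikx}$ decouple by mode, giving a
$2\times2$ stability matrix $J(k)$ whose entries involve only
$\hat w_{p1}, \hat w_{p2}, \hat w_s$ at $k$, $\sigma'(p_0)$ and the rates
(`stability_matrix()`). The dispersion relation — the leading eigenvalue
$\mathrm{Re}\,\lambda_+(k)$ — predicts which wavelengths grow, and the
eigenvector's sign structure classifies each mode as *in-phase* (population
and services grow together: city formation, $\sim$45–60 km at defaults) or
*out-of-phase* (they separate: within-city patterning, $\sim$4–5 km, which
requires both $\alpha_1 > 0$ and $a_p > 0$).

```{r dispersion}
disp <- dispersion_relation(model_params(), pbar = 8000)
glance(disp)
autoplot(disp)
```

For the base model the instability condition reduces to the closed form
$s_0(1-s_0)/(p_0 \sigma'(p_0)) + s_0 < 1 - s_0$, the unstable set is always
a single window $(0, k_c)$ — only sufficiently long wavelengths
destabilize — and the bifurcation value of $s_0$ solves
$s_0 = \mu(2s_0 - 1)\ln(1 - s_0)$, a one-dimensional root-find on
$(0, \tfrac12)$ (the product is positive only there; it is solved by 200
bisection steps, residual $<10^{-12}$). At $\mu = 3$, $\lambda = 20\,000$
this gives $s_0^* \approx 0.366$, $p_0^* \approx 15\,400$ persons
km$^{-2}$: above that density, perturbations smooth out (urban sprawl);
below it, cities form.

```{r bifurcation}
bifurcation_point(model_params())
```

A caveat on the competition variant: the innovation gate makes the service
equation nonsmooth exactly on the supply-demand balance set, where the
steady state sits. The per-mode matrix implemented here linearizes the
smooth supply-deficit branch ($H = 1$), which is the conventional choice
and the relevant one for growing perturbations; a two-sided derivative at
the kink would halve the innovator contribution to $J_{21}, J_{22}$. The
test suite's finite-difference oracle therefore expands about a state
displaced $10^{-4}$ below balance, on the smooth branch.

The out-of-phase band peaks at the minimizer of $\hat w_{p1}$, about
$k = 1.56$ rad km$^{-1}$ (4.0 km wavelength) at default $a_p = 1.5$,
$\beta_{p1} = 1$; we report the computed value (the package does not force
agreement with any externally quoted frequency).

## Time integration

Two integrators are provided. The default is an adaptive embedded
Runge-Kutta pair (deSolve's `ode45`, relative tolerance $10^{-6}$): at the
default rates (all $\le 2$ yr$^{-1}$) the nonlocal terms are nonstiff, so an
explicit pair is appropriate. A fixed-step classical RK4 is the second
path; the two agree to $<10^{-4}$ relative on test problems, and halving the
RK4 step changes final fields by $<10^{-4}$ relative. Large 2-D runs use
RK4 with $\Delta t = 0.1$–0.2 yr (the leading linear rates are
$\lesssim 0.1$ yr$^{-1}$, so this is far inside the stability region and
resolves the dynamics well; the step-halving check is part of the test
suite). Bounds are enforced after each step: negative overshoot of $p$ or
excursions of $s$ outside $[0,1]$ within a relative tolerance of $10^{-8}$
are clipped, anything larger aborts the run as a blow-up. Total population
is conserved to near machine precision by the movement operator itself
(the discrete exchange is exactly antisymmetric because the convolution
matrices are symmetric), so the conserved-mass trace in the history is a
pure diagnostic.

The strongest end-to-end check ties the integrator to the linear analysis:
seeding the homogeneous state with a single Fourier mode along the unstable
eigenvector, the log-amplitude of that mode grows at
$\mathrm{Re}\,\lambda_+(k)$ to within 2%.

Default domains are 200 km with 512 points in 1-D (chosen so the seven-bump
cosine initial condition $10\,000 + 5\,000\cos(7\pi x/100)$ fits exactly
seven periods) and $300\times300$ km with $256^2$ points in 2-D. Parameter
schedules (e.g. slowly widening kernels) are piecewise-linear interpolants
supplied as a `(time, parameter, value)` table; kernel transforms are
rebuilt when a schedule is active.

## Steady-state continuation

Patterned steady states are tracked in the mean population $\bar p$ by
pseudo-arclength continuation (`find_steady()`, `continue_branch()`). The
steady system on the grid has two structural degeneracies — conserved mass
and translation invariance. We remove them by (i) restricting to the even
cosine-symmetric subspace, the natural phase condition for a
reflection-symmetric problem, and (ii) replacing one redundant movement
equation by the constraint $\mathrm{mean}(p) = \bar p$. The service
equation enters through its smooth zero set
$\sigma(w_s * p) - s - \alpha_1 p = 0$ rather than the $(f+gs)$-weighted
rate, which conditions the Newton corrector much better; the service field
is kept among the unknowns (no adiabatic elimination), matching the
two-field linear analysis. The predictor is the secant through the last two
points, normalized in a scaled metric (population components and $\bar p$
scaled by the starting mean), so folds are traversed. Steps adapt between
bounds; every accepted point is re-verified by direct evaluation of the
dynamics (residual $< 10^{-9}$).

Stability of each point comes from the eigenvalues of the full $2N \times
2N$ dynamic linearization on the whole grid — odd perturbations included —
ignoring up to two structural neutral modes ($|\mathrm{Re}\,\lambda| <
10^{-8}$). Metastability is reported through the magnitude of the leading
eigenvalue rather than by brute-force millennial integration: the
seven-bump state, for example, carries a weakly unstable mode of order
$10^{-2}$ yr$^{-1}$, which grows from symmetric initial data's rounding
noise to visible amplitude only after $\sim10^3$ years.

At default parameters the single-bump branch on 200 km is stable from below
the subcritical bifurcation up to a fold at $\bar p \approx 18\,200$
persons km$^{-2}$ (grid-converged: 256 vs 512 points moves the fold by
$<0.1$%), beyond which only the homogeneous state is stable — a bistability
window between $\approx 15\,400$ and $\approx 18\,200$. The unstable return
branch shrinks in amplitude and terminates on the homogeneous state at the
bifurcation point, closing the loop with the analytic prediction.

## Length-scale estimators

Two estimators quantify the dominant spatial scale of a (simulated or
synthetic) field or point set.

**Moran correlogram.** For each separation bin $[d, d + \Delta)$
($\Delta = 1$ km by default, matching the 0–1 km, 1–2 km grouping of
centroid pairs), Moran's I with binary weights is
$$I(d) = \frac{N}{\sum_{ij} w_{ij}}\,
  \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}, \qquad
  w_{ij} = \mathbb 1\{d \le d_{ij} < d + \Delta\},$$
with $z$ the mean-centred values: the classic global-mean, binary-weight,
unnormalized-row variant. Point sets use direct pair enumeration with
Euclidean distances; periodic gridded fields replace pair enumeration by an
FFT autocorrelation binned by minimum-image radius, which is identical to
pair enumeration with periodic distances (validated against an explicit
double loop in the tests) at a small fraction of the cost. The dominant
length is the first local maximum beyond 5 km (skipping the trivial
self-correlation decay) whose prominence reaches 0.02 in I units, refined
parabolically across adjacent bins; further qualifying peaks are reported as
secondary, and a curve with no qualifying peak returns an explicit no-peak
result rather than an error.

One geometric subtlety: for an isotropic wave-like pattern in 2-D the
ring-averaged autocorrelation is a Bessel-$J_0$ profile whose first peak
sits at $\approx 1.12\times$ the plane-wave wavelength. A $\sim$46 km
linear pattern therefore yields a correlogram peak in the low 50s of km —
the two estimators answer slightly different questions ("typical
inter-cluster spacing" vs "dominant Fourier wavelength"), and we validate
planted-wavelength recovery on 1-D cosines and on 2-D city lattices, where
the peak location equals the planted scale.

**Transect power spectrum.** The mean-removed series along a uniformly
sampled line is Fourier-decomposed; power is reported per wavelength
(line length / harmonic) and the dominant wavelength is the argmax, flagged
as prominent only when the peak exceeds 10 times the mean spectral power
(white noise essentially never reaches this; a planted cosine at 2:1
amplitude over a competing mode always does).

```{r lengthscale}
g <- spatial_grid(180, 128, dimension = 2)
city <- field_city_lattice(g, spacing = 45)
glance(moran_correlogram(city, bin_width = 3))
```

## Synthetic data

All inputs are generated in code, seeded and bit-reproducible:
i.i.d. Gaussian noise fields (`field_noise`, e.g. $8000 + 1000\,
\mathcal N(0,1)$, with negative draws truncated at zero and the truncated
fraction reported — at the default mean/sd ratio truncation is vanishingly
rare, which is why truncation was chosen over rejection sampling), cosine
modes snapped to the periodic harmonics (`field_cosine`), square lattices
of Gaussian cities (`field_city_lattice`), random occupied patches
(`field_random_patches`, realizing "a constant density on 10% of the
domain" as seeded uniform cell selection), and irregular census-like point
sets with a planted city-lattice value pattern (`lsoa_like_points`, default
clustering pull 0.15 — strong clustering distorts bin composition at
mid-range distances and is deliberately mild so the planted scale stays the
first prominent peak).

These emulate the *statistical* structure the estimators need (planted
scales, noise, irregular sampling); they do not attempt realistic
geography — no coastlines, roads, or heterogeneous baseline density — so
passing round-trip tests demonstrates estimator correctness, not
performance on real census data.

## Problem sizes and numerical defaults

The package's standard analyses, as exercised by its tests and the
bundled acceptance script, use: dispersion relations on 512 wavenumbers
over $(0, 3]$ rad km$^{-1}$ (covering both the $\sim$0.1 city-scale and
$\sim$1.5 within-city regimes); continuation on 200 km / 512 points with
initial step 100 persons km$^{-2}$; emergence simulations on
$300\times300$ km / $256^2$ for 150 years (RK4, $\Delta t = 0.2$ yr) with
five independent noise seeds, summarized by the median correlogram peak.
Newton tolerances are $10^{-11}$ on scaled residuals; eigenvalue
neutrality threshold $10^{-8}$; peak prominence 0.02 in I units.

## Known limitations

- Parameters are homogeneous in space; time variation is supported only
  through the schedule hook.
- One population class and one service class; no disaggregation by income,
  service type, etc.
- The linear phase diagram classifies by the *dominant* mode; secondary
  patterning can persist nonlinearly in regions the linear analysis labels
  otherwise, as the simulations show.
- Stability flags sharper than the $10^{-8}$ neutrality threshold inherit
  the accuracy of the converged steady state; genuinely metastable states
  (leading eigenvalue $10^{-7}$–$10^{-2}$) are flagged unstable, with the
  eigenvalue reported so the user can judge the timescale.
- The Moran estimator's bins can be ragged for axis-aligned lattice
  patterns (angular anisotropy of the square grid); wider bins smooth this.
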