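---
title: "A coarse-grained proteome-allocation model of bacterial growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained proteome-allocation model of bacterial growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthlaws)
```

## The model

In balanced exponential growth every cellular constituent doubles at the
same rate, so the growth rate equals the specific rate of protein
synthesis. `growthlaws` implements a minimal model of this state built on
two constraints:

1. **Proteome partitioning.** Besides a growth-rate-independent
   housekeeping sector, the proteome divides into a ribosomal sector
   $\phi_R$ (ribosomes plus co-regulated translation factors) and a
   metabolic sector $\phi_P$ (transporters, catabolic and anabolic
   enzymes), with $\phi_R + \phi_P = \phi_R^{\max}$ fixed. Expanding one
   sector necessarily contracts the other.
2. **Amino-acid flux balance.** Translation consumes the free pool of the
   growth-limiting amino acid, with mass fraction $a$, at rate
   $\gamma(a)\,(\phi_R - \phi_R^{\min})$; metabolism replenishes it at
   rate $\nu(a)\,(\phi_R^{\max} - \phi_R)$. At steady state the two fluxes
   balance and the growth rate is
   $\lambda = \gamma(a^*)(\phi_R - \phi_R^{\min})$.

$\gamma$ is the *translational efficiency* (peptide elongation capacity
per unit ribosomal protein mass, units 1/h); the offset $\phi_R^{\min}$
absorbs inactive ribosomes. $\nu$ is the *nutritional efficiency* (supply
capacity per unit metabolic protein mass, 1/h), a lumped property of the
medium and of the expression and saturation of the supply pathways.

Both efficiencies depend on the pool itself. We model them as the
simplest sigmoids with the required limits,
$$\gamma(a) = \gamma_0\,\frac{a^{h_\gamma}}{K_\gamma^{h_\gamma} +
a^{h_\gamma}}, \qquad
\nu(a) = \nu_0\,\frac{K_\nu^{h_\nu}}{K_\nu^{h_\nu} + a^{h_\nu}},$$
i.e. Hill activation for translation (tRNA charging starves below
$K_\gamma$) and Hill inhibition for supply (end-product inhibition above
$K_\nu$). The exact functional forms are a modelling choice; any curves
with the same saturation limits give the same qualitative picture, which
is why figure-level comparisons in the tests are structural (limits,
monotonicity, half-points) rather than pointwise. The Hill exponents
default to 1 and are exposed for users who want sharper switches.

### Parameters

| name | meaning | default (presets) | units |
|------|---------|-------------------|-------|
| `gamma0` | maximal translational efficiency | 5.9 | 1/h |
| `nu0` | maximal nutritional efficiency | 2.5 (3.3, 5.8 = richer media) | 1/h |
| `K_gamma` | translation attenuation threshold | 1e-4 | mass fraction |
| `K_nu` | supply feedback threshold | 5e-4 (`narrow`) / 5e-3 (`wide`) | mass fraction |
| `phiR_min`, `phiR_max` | ribosomal fraction bounds | 0.07, 0.55 | fraction |
| `beta` | share of translation consuming the limiting amino acid | 1 | — |
| `h_gamma`, `h_nu` | sigmoid Hill exponents | 1 | — |

The numerical values are the standard calibration from E. coli
ribosome-profiling and RNA/protein measurements. `beta` rescales only the
pool dynamics (it cancels at steady state), so quoted `nu0` values can be
used unmodified; it defaults to 1.

## Steady states and the optimal allocation

For fixed $\phi_R$ strictly inside its bounds, the flux residual
$\nu(a)(\phi_R^{\max}-\phi_R) - \gamma(a)(\phi_R-\phi_R^{\min})$ is
strictly decreasing in $a$, so flux balance has a unique root $a^*$.
`solve_steady_amino_acid()` brackets it on a logarithmic axis (the pool
spans decades, from $10^{-6}$ to $10^{-1}$ in mass fraction) starting
from $[10^{-6} K_\gamma,\,10^{6} K_\nu]$ and expanding geometrically,
then polishes with `uniroot` to a relative tolerance of $10^{-12}$.
Degenerate allocations are handled explicitly: at $\phi_R^{\max}$ supply
vanishes identically and the continuous limit $a^*=0$ is returned; at
$\phi_R^{\min}$ consumption vanishes for *every* pool size, no finite
root exists, and the solver raises an error rather than inventing one.

The growth-rate profile $\lambda(\phi_R)$ vanishes at both bounds and has
a unique interior maximum. `optimize_allocation()` finds it with
`stats::optimize` (golden-section with parabolic interpolation) and
cross-checks against a 41-point grid, refining from the grid if the
scalar search was ever beaten (ties, which do not arise for this profile,
would resolve toward smaller $\phi_R$ — the cheaper proteome). The
closed-form plateau-limit optimum
$$\hat\lambda = \frac{\gamma_0 \nu_0}{\gamma_0 + \nu_0}
(\phi_R^{\max} - \phi_R^{\min}), \qquad
\hat\phi_R = \frac{\gamma_0\phi_R^{\min} + \nu_0\phi_R^{\max}}
{\gamma_0+\nu_0}$$
is the intersection of the two growth-law lines and bounds the true
maximum from above; the gap closes as $K_\nu/K_\gamma \to \infty$
(about 0.9% at a separation of $10^4$ with unit Hill exponents).

The **optimality plateau** is the range of pool sizes over which the
flux-balance curve $\phi_R^{bal}(a)$ stays within a stated fraction
(default 10%) of the optimal allocation. `plateau_band()` reports it both
in $a$ and in $\phi_R$; the 10% figure is conventional and exposed as
`rel_tol`.

## Regulation dynamics

Ribosome synthesis is regulated by allocating a fraction $\chi_R(a)$ of
active ribosomes to making ribosomal proteins (in E. coli this is the
ppGpp/rRNA axis: abundant amino acids mean high tRNA charging, low ppGpp,
de-repressed rRNA synthesis). Supply-driven activation means $\chi_R$ is
non-decreasing in $a$; `control_function()` validates this on
construction by dense sampling and supports Hill, piecewise-linear,
constant (the unregulated contrast) and user-table families. The
dynamics are
$$\dot a = \beta\left[\nu(a)(\phi_R^{\max}-\phi_R) - \lambda\right]
- a\lambda, \qquad
\dot\phi_R = \lambda\,(\chi_R(a) - \phi_R),$$
with $\lambda = \gamma(a)\max(\phi_R-\phi_R^{\min},0)$; the clamp keeps
transients below $\phi_R^{\min}$ well defined (they are growth-arrested:
$\dot\phi_R = 0$ there). The $-a\lambda$ term is dilution of the pool by
total protein mass growth. It follows from normalizing the pool by total
protein mass and is retained by default for exactness even though
$a \ll 1$ makes it a $\sim 10^{-4}$ relative effect; `dilution = FALSE`
drops it for pedagogical comparisons. Consistently,
`find_fixed_point()` by default solves the pool balance *including*
dilution, so the state it returns zeroes the right-hand side to machine
precision; with `dilution = FALSE` it reduces to the pure flux-balance
intersection $\chi_R(a) = \phi_R^{bal}(a)$, which is the exported
`phiR_balance()` curve used for the plateau. Because $\chi_R$ is
non-decreasing and the balance curve non-increasing, the intersection is
unique when it exists; when it does not, the error names which side of
the curve the control function sits on.

At the fixed point $\chi_R(a^*) = \phi_R^*$ exactly: if ribosomes are 25%
of the proteome in steady state, 25% of ribosomes are making ribosomes.
Stability is assessed numerically — a central-difference Jacobian
(relative step $10^{-6}$) kept numerical rather than symbolic so the rate
laws remain swappable — and both eigenvalues are found negative for every
admissible monotone control tested; an analytic global-stability proof is
outside the package's scope. `simulate_regulation()` integrates with the
stiff-capable `lsodar`, reports on a log-spaced time grid (the pool
relaxes in minutes, the composition over generations) and stops early via
a root function once $\|\dot x\|_\infty$ drops below the convergence
threshold.

The robustness claim is quantitative: with the `wide` preset
($K_\nu = 50 K_\gamma$), *any* monotone control function whose graph
crosses the optimality plateau lands on a stable steady state within 10%
of the optimal growth rate, across media ($\nu_0$). The test suite checks
this over a 50-member seeded family of Hill controls with randomized
baseline, amplitude, half-point and exponent, rejection-sampled to cross
the plateau. A constant (unregulated) $\chi_R$ tuned to one medium fails
in others: flux still balances, but the partition is wrong and growth is
translation- or supply-limited.

## Emergent growth laws, Monod kinetics and units

Where the plateau condition $K_\gamma \ll a^* \ll K_\nu$ holds, both
efficiencies sit at their maxima and the steady states obey the two
empirical linear growth laws:
$$\phi_R = \phi_R^{\min} + \lambda/\gamma_0 \quad
\text{(nutrient modulation)}, \qquad
\phi_R = \phi_R^{\max} - \lambda/\nu_0 \quad
\text{(translation inhibition)}.$$
`growth_law_sweep()` emulates both protocols — varying `nu0` across
media, or scaling `gamma0` down as an antibiotic proxy — and fits the
line with `fit_growth_law()` (ordinary least squares; the efficiency is
read off the slope with the law's sign). By default the sweep uses fixed
points of the *regulated* system with a generic Hill control centred at
$\sqrt{K_\gamma K_\nu}$: the point being demonstrated is that regulation,
not an optimizer, produces the laws. With the `wide` preset
(threshold separation 50) the law emerges with per-cent-level slope
accuracy; exact collinearity is approached only in the plateau limit, and
tests that assert it use a separation of $10^8$ or the closed-form
`method = "plateau"` sweep.

For transport-limited supply the transporter efficacy is Michaelis in the
external concentration, $k_a \propto a_{ex}/(K_M + a_{ex})$.
Substituting into the supply law and eliminating $\phi_R$ through
$\lambda = \gamma(\phi_R - \phi_R^{\min})$ yields the Monod relation
$$\lambda(a_{ex}) = \lambda_\infty \frac{a_{ex}}{a_{ex} + K_M^{app}},
\qquad
\lambda_\infty = \frac{\gamma\nu}{\gamma+\nu}
(\phi_R^{\max}-\phi_R^{\min}), \qquad
K_M^{app} = K_M\,\frac{\gamma}{\gamma+\nu},$$
the derivation implemented in `monod_params()`. The apparent Michaelis
constant is *smaller* than the transporter's own and carries the growth
medium dependence through $\gamma$ and $\nu$.

Mass fractions and concentrations interconvert through
$\phi_i = \sigma c_i N_{aa}$ with $\sigma = 3.8\times10^{-7}$ per µM per
residue (mean residue mass 110 Da, constant cell density). $\sigma$ is
stored at its conventional two significant figures, not re-derived.
All model I/O stays in mass fractions; conversion happens only at this
boundary.

## The synthetic-data generator

`generate_growth_table()` emulates a growth-law measurement campaign:
`n = 20` media drawn with $\nu_0 \sim U(0.5, 10)$ /h — growth rates of
roughly 0.2–1.8/h, doubling times from about 20 minutes to several hours,
the span actually accessible in batch culture — steady states computed on
the plateau-limit law line, and Gaussian noise of sd 0.01 added to
$\phi_R$ only (RNA/protein ratio assays carry most of the measurement
error; growth rates are comparatively precise). Tables are reproducible
from an integer seed (default 42) and the caller's RNG stream is left
untouched.

What the generator does *not* emulate: correlated condition-to-condition
systematics, departures from the law line at very slow growth (where the
active-ribosome offset itself becomes growth-rate dependent), and error
in $\lambda$. Passing recovery tests therefore certify the fitting
machinery under the model's own assumptions, not the model against real
measurements. A sobering consequence of the chosen noise level is worth
stating: with sd 0.01 on $\phi_R$ at $n = 20$, the OLS intercept standard
error is about 0.005, comparable to 7% of $\phi_R^{\min} = 0.07$, so the
intercept is at the edge of identifiability and single-seed recovery
within a few per cent is not statistically guaranteed — an inherent
property of these study conditions, visible in the test suite.

## Numerical choices and problem sizes

* Root finding on $\log a$ throughout; relative tolerance $10^{-12}$;
  brackets grown geometrically, never clamped silently.
* $\phi_R$ exactly at a bound is legal input (fluxes vanish
  continuously); outside the bounds is an error, not a clamp.
* Integrator: `lsodar`, `rtol = 1e-10`, `atol = 1e-14`, convergence
  event at $\|\dot x\|_\infty < 10^{-9}$.
* Test-suite problem sizes: 100-point $(\phi_R, \nu_0)$ solver grids, a
  50-member control-function family, 20 random starts for the
  convergence check, sweeps of 3–4 conditions — all chosen so the model's
  claims are exercised at full precision in seconds.

## Limitations

The model is a two-sector caricature: one limiting amino acid, no
explicit tRNA charging or ppGpp kinetics (the control function abstracts
them), no nutrient-shift or single-cell stochastic dynamics, and no
evolutionary adaptation of $\gamma_0$ or $\nu_0$. The allocation problem
is one-dimensional by construction; multi-sector allocation and
stoichiometric FBA are out of scope.
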