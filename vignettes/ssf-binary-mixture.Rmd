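---
title: "The single-step function of a binary isotropic-Poisson mixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The single-step function of a binary isotropic-Poisson mixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfmix)
```

## The model

Monte Carlo photon-transport codes need, at every step, the probability
density of the distance a photon travels in a straight line before its next
interaction — the *single-step function* (SSF). In a homogeneous medium with
extinction coefficient $\mu_t$ this is the Beer–Lambert law
$p(s)=\mu_t e^{-\mu_t s}$. Many media of practical interest (tissue-like
composites, clouds, reactor fuels) are instead *binary statistical
mixtures*: along any ray the photon alternately traverses contiguous regions
("tessels") of two materials $a$ and $b$, each with its own extinction
coefficient $\mu_{t_a}$, $\mu_{t_b}$.

For an isotropic Poisson tessellation the chord that a tessel contributes to
a ray is exponential, $p(\ell)=\sigma e^{-\sigma\ell}$, with inverse mean
chord $\sigma_a$ or $\sigma_b$; isotropy ties the two rates to a
construction scale $L$ and a mixing probability $P$ through
$\sigma_a=(1-P)/L$, $\sigma_b=P/L$ (`isotropy_sigmas()`). The package does
not assume this constraint anywhere downstream — the step law is valid for
any four rates.

The SSF of the mixture is assembled exactly from three ingredients:

1. **Jump counts.** The probability of crossing one whole tessel is
   $\sigma/(\sigma+\mu_t)$ per material; alternating these factors and
   appending the stop factor gives the three-branch probability mass
   function of the number $N$ of tessels crossed (`pmf_jump_count()`), a
   proper distribution for every parameter set.
2. **Path lengths.** Conditional on crossing $N$ tessels and stopping in
   the $(N+1)$-th, the step length is the sum of $N+1$ alternating
   exponential chords with composite rates $r_a=\mu_{t_a}+\sigma_a$ and
   $r_b=\mu_{t_b}+\sigma_b$ — a two-rate hypoexponential whose closed form
   involves modified Bessel functions $I_\nu$ of half-integer order in the
   rate contrast $\mu=r_b-r_a$ (`pdf_tessel_sum()`).
3. **Mixing.** Summing over $N$ with the jump-count weights gives the
   fixed-start-type density (`pdf_ssf_one_start()`), and weighting the two
   start types by $1-P$ and $P$ gives the mixture SSF, `pdf_ssf_mix()`.

With the SSF in hand the random binary medium can be *replaced by one
equivalent homogeneous medium*: a quantile look-up table of the SSF
(`build_quantile_table()`) turns uniform deviates into steps
(`simulate_equivalent_homogeneous()`) with exactly the mixture statistics,
so one Monte Carlo run substitutes for an ensemble of runs over random
tessellations. The companion quantities are the mean step length
`mean_step_mix()` (closed form), the effective albedo `albedo_mix()`
(occupation-weighted scattering over extinction), and the fixed-start law
`pdf_ssf_fixed()` for photons launched from a source or boundary rather
than from an interaction point.

## Parameters and units

All rates ($\mu_{t}$, $\sigma$) are quoted in inverse millimetres and
lengths in millimetres; the mathematics is unit-free, so any consistent
pair works. `mixture_params()` enforces the domain: non-negative rates, at
least one positive extinction coefficient (otherwise the mean step is
infinite), strictly positive composite rates, $P\in[0,1]$. The rate
contrast $\mu$ may take any sign; every code path is well-defined for
$\mu<0$, $\mu=0$ and $\mu>0$.

`series_control()` holds the numerical policy: `epsilon_tail` (default
`1e-10`) bounds the probability mass neglected when the infinite sum over
$N$ is truncated — the truncation point comes from the geometric tail bound
with per-pair ratio $\frac{\sigma_a}{r_a}\frac{\sigma_b}{r_b}$
(`jump_count_truncation()`); `quad_rel_tol` (default `1e-10`) is the
adaptive-quadrature tolerance used for distribution functions and moments.
The truncation residual is deliberately *not* rescaled away: rescaling
would mask truncation bugs, so the density is reported as computed and
`ssf_diagnostics()` exposes the neglected mass.

## Numerical choices

**Bessel evaluation.** The closed forms contain
$\mu^{-\nu} I_\nu(s\mu/2)$, which is awkward when $\mu \le 0$. The package
evaluates everything through $h_\nu(t)=I_\nu(t)/t^\nu$, an *even entire*
function of $t$: its power series (used for $|t|\le 30$; all terms
positive, accumulated relative to the leading term, so no cancellation,
underflow or overflow) depends only on $t^2$, and its limit
$2^{-\nu}/\Gamma(\nu+1)$ at $t=0$ makes the equal-rate degeneracy
($\mu\to 0$, where the law collapses to a gamma density) exact without any
branch. For $|t|>30$ the exponentially scaled `besselI` is recombined in
log space; beyond $x\approx 10^4$, where base R's Bessel underflows, the
exact finite Hankel sums for half-integer orders take over (all orders
arising here are half-integers). For the odd-$N$ form with $\mu<0$ the two
Bessel terms nearly cancel at large $|t|$; the difference is taken between
the scaled values, which bounds the relative error by roughly
$\varepsilon\,|t|/\nu$. All prefactors (powers of the rates, $s^{N-1}$,
$e^{-\bar r s}$) are assembled in log space and exponentiated once, keeping
the evaluation finite for $s\,\max(r_a,r_b)$ well beyond 700.

**Distribution function and quantiles.** `cdf_ssf_mix()` integrates the
density with adaptive quadrature (exact reference path);
`build_quantile_table()` instead runs one vectorised composite
Gauss–Legendre pass on a dense grid, then inverts onto equally spaced
probability levels, so the tabulation error is uniform in probability. The
table (default 4096 nodes) is interpolated with a monotone piecewise-cubic
(Fritsch–Carlson) rule in both directions, which preserves monotonicity by
construction; its coverage is required to reach $1-10^{-8}$. Quantile
requests beyond coverage raise a typed tail error; the sampler's default
policy is to redraw such deviates.

**Cumulative chord functions.** The fixed-start machinery needs
$F(s;N)=\int_0^s p_{\text{tes}_N}$. The canonical path is quadrature of the
Bessel form. The finite hypergeometric closed forms are available behind
`fixed_start_config(use_closed_form_F = TRUE)` (default off): the odd-$N$
expression contains generalized binomial coefficients with negative lower
index, which vanish under the integer convention and are dropped *together
with* the non-terminating hypergeometric factors they multiply; with that
convention the closed forms agree with quadrature to $\sim 10^{-12}$ for
$N\le 8$ and both signs of $\mu$. Because the terms carry
$(-\mu)^{k-N}$, the closed forms lose accuracy as $\mu\to 0$ (the
$\mu = 0$ case short-circuits to the gamma distribution function); every
closed-form value is therefore cross-checked against quadrature and a
disagreement beyond $10^{-6}$ raises a typed consistency error instead of
returning silently.

**Fixed-start law.** `pdf_ssf_fixed()` is computed as
$(1-\text{CDF}(s))/\langle s\rangle$ — the unambiguous survival-function
definition — rather than through the expanded series form, whose printed
numerator mixes the two start-type terms with inconsistent signs. A useful
consequence checked in the tests: the infinite-chord limit of the
fixed-start law is the *survival* mixture
$\frac{\mu_{t_a}\mu_{t_b}}{(1-P)\mu_{t_b}+P\mu_{t_a}}
\left[(1-P)e^{-\mu_{t_a}s}+P e^{-\mu_{t_b}s}\right]$,
which integrates to one (a form with the rate factors repeated inside the
bracket does not, and is therefore not a valid limit of a pdf).

## The Monte Carlo validators

`simulate_direct_steps()` is the reference experiment: per photon, draw the
first-tessel type with the strict rule $\xi < 1-P$, then alternate
chord/candidate-step draws until the candidate step falls short of the
chord; a fresh tessellation is drawn for every photon (equivalent, for
step statistics, to averaging over an ensemble of frozen configurations).
Exponential deviates use the inverse transform $-\log(1-\xi)/\text{rate}$
so that $\xi=0$ stays finite. One seedable base-R generator drives each
simulation call; draws are made in round-major vectorised order (all
still-active photons per iteration), so results are bit-reproducible given
the seed and photon count. `simulate_interior_start()` demonstrates the
memorylessness that underpins the whole construction: residual chords seen
from an interior point are again exponential with the material's own rate.

What the simulators *emulate* is exactly the one-dimensional chord process
along a ray — which is all the step law depends on. What they do not
emulate: angular scattering (phase functions), refractive-index mismatch
between tessels, or spatially correlated three-dimensional geometry beyond
the Poisson chord statistics. Passing validation therefore shows that the
analytic SSF is the correct step kernel for such media, not that any
particular 3-D geometry is Poissonian.

## Validation set-up and problem sizes

The test suite validates each layer against an independent oracle:
jump-count probabilities against brute-force products of crossing factors;
Bessel-form densities against matrix-exponential evaluations of the
absorbing chain and against FFT grid convolutions with Richardson
extrapolation; the full series against a two-state phase-type closed form;
moments against quadrature. The Monte Carlo comparisons use
Kolmogorov–Smirnov tests at the 1% level on $10^6$ photons for the direct
walk (four regimes spanning $\mu<0$, $\mu\approx 0$, $\mu>0$ and
$P\in\{0.2,0.5,0.8\}$), $10^5$ residual chords per depth for the
interior-start check, and $10^5$ steps per arm for the two-sample
equivalence of the look-up-table sampler and the tessellated walk — sizes
chosen so each check resolves percent-level distributional errors while
the whole suite runs in minutes on one core.

## Known limitations

* The closed-form cumulative functions degrade near $\mu=0$ and are kept
  behind a validation gate; the quadrature path is the contract.
* Albedo and step law are provided as kernels for transport codes; the
  package does not itself track scattering angles or run full radiative
  transfer.
* Reproducibility of the simulators is tied to the documented vectorised
  draw order; per-photon RNG substreams are not implemented.
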