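---
title: "Analytical propagators for telegraph models of gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical propagators for telegraph models of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propgf)
```

## The problem

Single-cell time-lapse experiments deliver protein-abundance time series
$(t_i, n_i)$ sampled at a fixed interval $\Delta t$. Comparing stochastic
gene-expression models against such data requires the *propagator*
$P_{n'|n}(\Delta t)$ — the probability of observing $n'$ molecules a time
$\Delta t$ after observing $n$ — for arbitrary parameter values, because the
transition log-likelihood of a parameter set $\Theta$ is
$L(\Theta) = \sum_i \log P_{n_{i+1}|n_i}(\Delta t)$. The sampling interval is
typically *short* relative to the protein lifetime, so stationary or
long-time approximations are not applicable; and brute-force stochastic
simulation for every candidate $\Theta$ is expensive. This package evaluates
the propagators analytically, through closed-form (perturbative)
probability-generating functions that are inverted numerically by Cauchy
contour integration.

Two model families are covered, both formulated as chemical master
equations (CMEs) for a gene switching between an inactive state $D$ and an
active state $D^*$:

* **Model A** (autoregulated telegraph model): the active gene produces
  protein at rate $p_b$; protein decays at rate $p_d$; switching rates are
  $c_f$ (on) and $c_b$ (off). Protein feeds back on its own expression by
  promoting activation (rate $a$) or deactivation (rate $r$). Time is
  nondimensionalised by $p_d$, giving $\kappa_f, \kappa_b, \lambda$ and a
  small feedback parameter $\delta$ with $a = \alpha p_d \delta$ (or
  $r = \rho p_d \delta$).
* **Model B** (two-stage telegraph model): the active gene is transcribed to
  mRNA (rate $\nu_0$), mRNA is translated (rate $\nu_1$), and both species
  decay ($d_0$, $d_1$). Time is nondimensionalised by $d_1$; the key small
  parameter is $\varepsilon = d_1/d_0$, the ratio of protein to mRNA decay
  rates, which is small in many microbial systems because mRNA is
  short-lived. $\mu = \nu_1/d_0$ is the mean translational burst size.
  Feedback can act through mRNA or protein on either switching channel, again
  with a small parameter $\delta$.

## The method

Three transformations reduce each CME to something solvable:

1. **CME to PDE.** The gene-state-resolved generating functions
   $F^{(j)}(z,t) = \sum_n z^n P^{(j)}_n(t)$ (and the two-variable analogue
   $F^{(j)}(w,z,t)$ for model B) satisfy coupled first-order linear PDEs.
2. **PDE to ODE.** The method of characteristics converts the transport
   operator into $d/ds$ along curves $v(s) = v_0 e^s$ (with $v = z-1$); for
   model B the mRNA coordinate $u = w-1$ obeys a fast equation
   $\varepsilon \dot u = u - \mu v (u+1)$, a slow–fast system whose critical
   manifold $u = \mu v/(1-\mu v)$ is normally repelling.
3. **ODE to closed form.** For model A the characteristic system collapses
   to Kummer's equation: the two homogeneous solutions are
   ${}_1F_1(\kappa_f; 1{+}\kappa_f{+}\kappa_b; w)$ and
   $w^{-\kappa_f-\kappa_b}\,{}_1F_1(-\kappa_b; 1{-}\kappa_f{-}\kappa_b; w)$
   in $w = \lambda v_0 e^s$. For model B the fast-time expansion in
   $\varepsilon$ yields polynomial-plus-exponential coefficients.

Initial data need one extra parameter: the probability $\chi$ that the gene
is *off* at time zero given the observed molecule counts, because a single
observed count does not determine the gene state. By default $\chi$ is
derived from the switching (and feedback) propensities evaluated at the
initial counts ("Markov" mode, `chi_markov()`); a fixed value or explicit
series coefficients can be supplied instead (`chi_spec()`).

Finally, probabilities are recovered from the Cauchy integral
$P_n = \frac{1}{2\pi i}\oint F(z)/z^{n+1}\,dz$ discretised on a circle,
which is exactly a discrete Fourier transform of the contour samples
(`invert_1d()`, `invert_2d()`). One set of contour samples yields the whole
propagator column.

## Feedback as a regular perturbation

Autoregulation couples the two gene states through $z\partial_z$ (or
$w\partial_w$) terms and breaks the common characteristic structure. Because
measured feedback rates are typically small relative to decay rates, the
package expands in $\delta$: the order-$\delta$ coefficients solve the same
characteristic equations with a source built from the leading order. For
model A the correction is computed two independent ways — variation of
constants with hypergeometric-weighted integrals along the characteristic
path (default), and direct complex ODE integration — which agree to
$\sim 10^{-10}$ and protect against branch-convention mistakes: the paths
are parametrised so that consecutive points differ by *real* exponential
factors, and the $w^{-\kappa_f-\kappa_b}$ factors combine into
$e^{-(\kappa_f+\kappa_b)s}$, so no fractional powers of $z-1$ ever arise.

The lower limits of the variation-of-constants integrals are chosen so that
the particular solution vanishes at $s=0$, with the homogeneous constants
then fixed by the order-$\delta$ initial data; this choice provably satisfies
the initial conditions and is validated by the ODE route.

The derivative of the leading order with respect to the characteristic base
point, needed in the source, is computed by a trapezoidal Cauchy-ring rule on
a small circle (16 nodes, radius 0.05). The integrand is entire in the base
point, so this derivative is spectrally accurate; a complex-step scheme is
not applicable because the argument is already complex.

## Keeping the slow–fast composition bounded

For model B the fast-time series coefficients contain factors
$e^{(1-\mu v_0)\sigma}$, and the perturbative inverse characteristic map
contains $e^{(\mu v - 1)\sigma}$. Composed naively and evaluated at
$\sigma = t/\varepsilon \gg 1$ these products overflow and, worse, the
truncation residues are amplified exponentially: the expansion is a
Poincaré expansion, valid term by term only for $\sigma = O(1)$. The package
therefore evaluates an algebraically equivalent *resummed* form in which
every exponential is combined before $\sigma = t/\varepsilon$ is inserted:

* the backward-flow contraction factor is
  $\exp\{[\mu v(1-e^{-t}) - t]/\varepsilon\}$ (modulus $\le e^{-t/\varepsilon}$);
* the slow production integrals are evaluated in closed form along the
  *moving* characteristic:
  $\int_0^\sigma u\,d\sigma' = \varepsilon^{-1}\ln(q_0/q) +
  \tfrac1{2q^2} - \tfrac1{2q_0^2} + \text{(boundary layer)}$, with
  $q = 1-\mu v$, $q_0 = 1 - \mu v e^{-t}$, and the double integral involves
  the complex dilogarithm;
* the constant-rate switching relaxation is resummed into
  $g_1\,[1 - e^{-(\kappa_0+\kappa_1)t}]/(\kappa_0+\kappa_1)$;
* the production channel of the on-state component is resummed
  exponentially, $F^{(1)} = (F^{(1)}_0 - G)\,
  e^{\varepsilon\lambda \int u}$;
* at the top expansion order the total generating function is assembled
  through the exact identity $F = \Phi + \lambda\int_0^t u(s)F^{(1)}(s)\,ds$
  (Gauss–Legendre on the smooth part, closed-form layer term), which
  restores the correct operator ordering between switching and production.

Each replacement agrees with the frozen-base-point series term by term at the
working order (verified against coefficient extraction from the exact
characteristic solution) while remaining bounded for all $t$. Two exact
structural identities survive the resummation and serve as self-tests: the
total mass $F^{(0)}+F^{(1)} = 1$ at $z = w = 1$ holds *exactly* at every
order, and $t \to 0$ reproduces $\chi\,w^{m_0}z^{n_0}$ exactly.

The slow-segment composite expansion is deliberately not implemented: the
critical manifold is normally repelling, so backward-mapped base points are
exponentially sensitive and a slow-segment series would introduce
exponentially large terms.

For feedback in model B, the order-$\delta$ pair on a characteristic obeys a
constant-coefficient switching system driven by the feedback source in the
antisymmetric direction $(-1, +1)$, which the stationary projector of the
switching matrix annihilates; the correction therefore relaxes with rate
$\kappa_0+\kappa_1$, is carried through the production channel by the same
resummed integral, and conserves probability exactly. The leading fast-time
source coefficient has the elementary form
$c_e e^{-q_0\sigma'} + c_0 + c_1\sigma'$ in all four feedback channels.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `delta` | scaled feedback rate (per decay rate) | — | expansion requires `delta < 1`; warning otherwise |
| `eps` | protein/mRNA decay-rate ratio | — | `eps < 1` assumed; warning otherwise |
| `eps_order` | depth of the fast-time expansion | 2 | order 0 is the frozen leading-order closed form |
| `chi` | initial off-state probability | Markov | `chi_spec()` for fixed / series modes |
| `radius_z` | inversion contour radius | 1 (A), `min(1, 0.75(1+1/mu))` (B) | model-B GF has a pole at `z = 1 + 1/mu`; radius ≤ 1 always suffices |
| `nodes_z` | contour nodes | smallest power of 2 ≥ max(64, 4(n_max+1)) | spectral accuracy; FFT-friendly |
| `nq` | Gauss–Legendre nodes (order-δ and order-ε² integrals) | 64 / 24 | integrands are analytic in the integration variable |

Numerical edge cases: when $\kappa_f+\kappa_b$ lies within $10^{-6}$ of a
positive integer, the hypergeometric denominator parameters
$1\pm(\kappa_f+\kappa_b)$ degenerate; the solution is continuous in the
parameters, so $\kappa_f$ is nudged by a relative $10^{-8}$ (with a message).
Contour points within $10^{-8}$ of the model-B pole are an error, not a
silent regularisation. Negative propagator entries from truncated
asymptotics are reported, not clipped (use `clip = TRUE` to renormalise);
they are a useful diagnostic of expansion error. Probabilities are floored
at $10^{-300}$ before logs in the likelihood, with a count of floored
transitions.

The ${}_1F_1$ evaluation uses the series with the Kummer transformation
$M(a,b,x) = e^x M(b-a,b,-x)$ for $\mathrm{Re}\,x<0$, which removes the
dominant cancellation; residuals of the Kummer ODE are monitored in the test
suite. An arbitrary-precision fallback is not available in this environment,
which bounds usable arguments to moderate $|\lambda(z-1)|$ (roughly
$\lambda \lesssim 50$ on the unit contour).

## What the oracles and the generator do (and do not) show

`fsp_propagate()` integrates the truncated CME (finite state projection)
with sparse generators and a posteriori boundary-occupancy checks;
`ssa_simulate()` is a direct-method Gillespie implementation of the full
reaction schemes including each feedback channel, with per-path substreams
derived from one master seed. `synth_series()` emulates the measurement
process the likelihood front end expects: one trajectory, protein counts
only, sampled at a fixed interval. It does *not* emulate measurement noise,
cell division, extrinsic rate fluctuations, or non-uniform sampling — so
passing tests demonstrate correctness of the propagator machinery under the
model's own assumptions, not adequacy of the model for any particular
data set.

## Accuracy regimes and known limitations

* Model A at $\delta = 0$ is exact (agreement with FSP is at solver
  precision, $\sim 10^{-9}$); with feedback the remainder is $O(\delta^2)$ —
  log–log slopes $\approx 1.9$ against FSP over $\delta \in [0.025, 0.1]$.
* Model B carries an intrinsic *fixed-$t$ secular residue*: terms
  $\varepsilon^n\sigma^n = t^n$ make the truncated expansion Taylorise the
  slow switching/production dynamics, so as $\varepsilon \to 0$ at fixed $t$
  the error plateaus at $O((\text{slow rate}\cdot t)^3)$ unless those
  channels are resummed. The resummations above remove the pure-switching
  and pure-production parts; the remaining floor is set by third-order
  switching–production cross terms, noticeable when
  $(\kappa_0+\kappa_1)t \gtrsim 3$. The $\varepsilon$-convergence study in
  the acceptance suite therefore uses moderate rates
  ($\kappa_0 = 0.3$, $\kappa_1 = 0.4$, $\lambda = 0.5$, $\mu = 1.5$,
  $m_0 = n_0 = 3$, $t = 1$), where the measured slope is $\approx 1.2$; in
  strong-switching regimes the error is dominated by the
  $\varepsilon$-independent floor and does not decrease further.
* The model-B feedback correction is first order in $\delta$ with its source
  evaluated at the frozen base point; its own error is
  $O(\varepsilon) + O(\delta)$ relative, so the $\delta$-convergence study
  uses $\varepsilon = 0.02$ and $t = 0.3$ (measured slope $\approx 1.85$).
* Problem sizes used by the automated studies (state-space truncations of
  60–90 for model A, $16 \times 34$ for model B, $10^4$–$2\times10^4$
  simulation paths) were chosen so that oracle error is negligible relative
  to the quantities being measured.

## A worked example

```{r example}
p <- model_a_params(kappa_f = 0.5, kappa_b = 1, lam = 2)
gf <- function(z) {
  g <- eval_gf_a(p, n0 = 5, z = z, t = 1)
  g$total_F0 + g$total_F1
}
tab <- invert_1d(gf, n_max = 15, t = 1, n0 = 5)
round(tab$P, 5)
tab$mass

ref <- fsp_propagate("A", p, 5, t = 1)
max(abs(tab$P - ref$P[1:16]))

s <- synth_series("A", p, n0 = 5, dt = 0.5, n_samples = 10, seed = 1)
log_likelihood(s, "A", p)
```
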