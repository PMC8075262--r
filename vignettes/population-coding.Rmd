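---
title: "Efficient population coding under input and output noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient population coding under input and output noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(popcoding)
```

## The model

A population of $N$ thresholding neurons encodes a scalar stimulus $s \sim
P(s)$ (standard normal by default; a generalized normal with shape $\beta$
when heavier or lighter tails are wanted). Each neuron is binary with rate
levels $\{0, \nu_{\max}\}$ and threshold $\theta_i$. Two noise sources
corrupt the code:

* **Input noise** — additive noise $z$ of standard deviation $\sigma$ (in
  stimulus units) enters before the nonlinearity, so the *effective* tuning
  curve is the sigmoid $H_i(s) = P(s + z \ge \theta_i)$; for Gaussian noise
  this is the probit $\Phi((s-\theta_i)/\sigma)$, and $\sigma = 0$ gives a
  Heaviside step.
* **Output noise** — spike generation in the coding window $\Delta T$ is
  Poisson. Its severity is summarized by $R = \nu_{\max}\Delta T$, the
  expected count at maximal rate: small $R$ means a silent window is likely
  even when the neuron is driven.

Two readouts are compared. The *independent-coding channel* transmits the
count vector $(k_1, \dots, k_N)$; because the rate is binary, every count
$k_i \ge 1$ proves the neuron was driven, so each neuron collapses exactly
to a Bernoulli output with $P(k_i = 0 \mid s) = (1 - H_i) + e^{-R} H_i$.
The *lumped-coding channel* transmits only the sum $k = \sum_i k_i$, whose
kernel is built by exact recursive convolution of the per-neuron full-count
distributions, truncated where the Poisson($NR$) upper tail falls below a
tolerance (default $10^{-10}$). Mutual information is computed as output
entropy minus noise entropy; terms with zero probability contribute zero.
The sum is a function of the vector, so the lumped channel can never carry
more information — a property the test suite checks on random draws.

## Numerical choices

* **Quadrature.** Stimulus integrals use a fixed composite Simpson rule on
  $[\mu - 8\,\mathrm{max}(\sigma_s,\sigma),\ \mu + 8\,\mathrm{max}(\sigma_s,
  \sigma)]$ with 801 points by default. A fixed rule keeps the information a
  smooth deterministic function of the thresholds, which the optimizer and
  the criticality analysis depend on. When $\sigma$ is positive but smaller
  than a few grid steps, fine panels are inserted around each threshold and
  the merged grid is integrated with the trapezoid rule. With $\sigma = 0$
  no quadrature is used at all: the integrals reduce exactly to finite sums
  over the $N+1$ inter-threshold regions. For the broad sigmoids of the
  auditory-nerve application the information is converged to eight decimals
  already at 201 points, so the heavy three-neuron searches run on reduced
  grids (stated below).
* **Truncation.** Summed-count and full-count channels truncate Poisson
  tails at mass $10^{-10}$ ($k_{\max} \approx 45$ at $R = 13.8$); the
  truncation actually used is recorded in every evaluation object.
* **Zero-probability states.** $0 \log 0 := 0$ throughout; in log-domain
  products the logs are capped below at $-10^4$ so that impossible states
  stay finite and contribute exactly zero.

## Symmetries — which are exact and which are not

Permuting thresholds never changes either channel, so optimized thresholds
are reported sorted. The mirror map $\vec\theta \to -\vec\theta$ is *not* an
exact symmetry at finite $R$: a silent window is ambiguous (undriven, or
driven but unlucky), and mirroring swaps the roles of the ambiguous and
unambiguous states rather than relabeling outputs. The asymmetry scales
with $e^{-R}$ (and with the spontaneous-rate mixture in the auditory-nerve
model, where it is a few times $10^{-4}$ nats near the optima at
$R = 13.8$). Consequently:

* the optimizer does not fold mirror solutions onto a canonical half-space;
  determinism comes from its fixed start grid;
* the landscape search uses the half-space trick only for the coarse pass
  and re-evaluates mirrored candidates exactly;
* the test suite asserts mirror equality only at large $R$ (where it holds
  to $10^{-9}$) and asserts a *genuine* asymmetry at small $R$, so the
  property is documented rather than silently assumed.

## Optimization

The information landscape is multimodal: near-mirror twins at low output
noise, and, for the lumped channel, genuinely distinct local maxima whose
exchange of global status produces discontinuous threshold jumps. The
optimizer is deterministic multistart local search: Nelder-Mead (the
default; no gradients, robust where the Hessian degenerates near critical
noise) from every sorted combination-with-repetition of the stimulus
quantiles at levels $1/(N{+}1), \dots, N/(N{+}1)$, plus the all-equal
start. Replicated-threshold starts sit exactly on the merge manifolds and
catch the redundant-coding optima. BFGS is available for the lumped
channel, whose Hessian stays well conditioned through its (first-order)
transitions; it is roughly four times faster there and is used for the
heavy three-neuron noise sweeps. Convergence tolerances: $10^{-10}$
relative on information (tightened to $10^{-13}$ for near-critical work),
with one polish restart from the incumbent.

Noise scans re-optimize along a monotone noise grid with warm starts from
the neighbouring point *plus* the cold multistart grid — warm starts track
continuous branches, cold starts catch the lumped channel's discontinuous
jumps between local maxima.

## Criticality analysis

The number of distinct optimal thresholds (single-linkage clustering with
gap tolerance $\tau_\theta = 10^{-3}$ stimulus SD) drops as either noise
grows. A change along a scan brackets a critical noise level, which
`detect_critical_noise()` refines by bisection with re-optimization to a
relative width of $10^{-4}$ (tightened to $10^{-5}$ before exponent fits:
a bias $\delta$ in the critical value tilts the log–log fit by roughly
$\delta / (x_c \cdot 10^{-3})$ at the inner edge of the window).

The Hessian of the information with respect to the thresholds is computed
by central differences with one Richardson step (base step $10^{-3}$),
then eigendecomposed. At a continuous merge of $M$ thresholds the
landscape flattens along the ridge $\sum \theta_i = \text{const}$, so
$M-1$ eigenvalues approach zero and the soft eigenvectors are orthogonal
to $(1,\dots,1)/\sqrt{M}$; for the lumped channel the spectrum stays
bounded away from zero through the jump.

Transition order follows the Ehrenfest convention on the maximized
information: one-sided quadratic fits estimate the first derivative on
each side of the critical value; a jump larger than ten times the fit
noise floor means first order, otherwise the second-derivative jump is
examined and the transition is second order. Critical exponents are
least-squares slopes of $\log(\Delta\theta)$ (or $\log|\lambda|$) against
the log relative distance inside a window of relative distances
$[10^{-3}, 5\times 10^{-2}]$ by default; the window, side, point count and
standard error are part of the result.

## Auditory-nerve application

Rate-intensity curves are modelled as
$\nu_i(s) = r_i + (r_{m,i} - r_i) H_i(s)$ on the standardized intensity
axis $s = (\text{level}_{\mathrm{dB}} - 30)/12.5$ (a Gaussian sound-level
distribution with mean 30 dB SPL and SD 12.5 dB). With a nonzero
spontaneous rate the binary collapse is invalid, so the channel uses full
Poisson counts: conditional on the stimulus each count is the mixture
$(1-H_i)\,\mathrm{Pois}(R\rho_i) + H_i\,\mathrm{Pois}(R)$ with
$\rho_i = r_i / r_{m,i}$ and $R = 13.8$ (average maximal rate times
$\Delta T = 50$ ms; the same $R$ is reused for the three-neuron model,
recorded here as an assumption). Information is reported in nats for this
application and in bits for the binary theory, matching the units in which
such results are usually quoted; a `log_base` argument controls the
output.

Fitting uses Levenberg–Marquardt least squares with data-driven starts
(floor, plateau, half-rise level, 10–90% span) and a few scale-perturbed
restarts; flat curves return a failure record, and fits whose samples do
not visit both the floor and the plateau are flagged low-confidence. Fiber
types use the cumulative-distribution rule: $D_i = F(\rho_i) - F(\sigma_i)$,
positive $D_i$ being type 1. The three-way split cuts $D_i$ at tertiles —
the natural extension of the two-way sign rule, recorded in the output as
a package decision since only the two-way rule is standard. An optional
robust-z outlier filter on $\rho$ (median/MAD, cutoff 4) is available but
disabled by default: synthetic cohorts have no recording artefacts.

Information per spike divides the information by the stimulus-averaged
expected total count $\int P(s) \sum_i \nu_i(s)\Delta T\, ds$. Alternative
mean-rate conventions (e.g. unweighted averages over a level range) exist;
this stimulus-weighted definition is the one the per-spike reference
values reproduce, and we make no attempt to match relative-rate figures
quoted under other conventions.

The landscape search evaluates a coarse grid (step 0.25 for two neurons,
0.3 for three, bounds $\pm 3$ and $\pm 2.7$ stimulus SD), keeps the top
points merged into local-maximum candidates, refines each by halving the
step (three rounds, a $5^N$ stencil per round), and polishes with
Nelder-Mead. Quadrature uses 401 points for two neurons and 201 for three
(both converged to well below the reported precision, as noted above).

## The synthetic cohort generator

`generate_cohort()` draws per-fiber parameters from truncated multivariate
normals within each type (defaults: the two-type means above; within-type
correlations $\mathrm{corr}(\rho,\sigma) = -0.5$,
$\mathrm{corr}(\sigma,\theta) = +0.5$, $\mathrm{corr}(\rho,\theta) =
-0.25$, chosen to reproduce the qualitative structure seen in real fiber
populations), assigns fibers round-robin to animals, and samples rates on
a 0–80 dB grid in 5 dB steps as sigmoid mean plus homoscedastic Gaussian
noise (SD 5 Hz, clipped at zero) — the simplest defensible measurement
model; a Poisson-count alternative is available by flag. Everything is a
pure function of the spec and its seed.

What the generator does *not* emulate: frequency tuning (curves are
already projected onto the best-frequency intensity slice), adaptation and
rate saturation drift within a recording, level-dependent measurement
variance, and recording artefacts. Passing recovery and classification
tests on these cohorts therefore validates the fitting and typing
machinery, not the biological completeness of the generative model.

## Problem sizes used by the shipped analyses

The packaged tests and the reproduction script keep runs small enough for
a laptop: two-neuron optimizations everywhere possible; the three-neuron
advantage sweep on a seven-point output-noise grid at $\sigma = 0.01$;
exponent fits from 12–20 optimizations per axis inside the fit window; and
the three-neuron landscape at the reduced quadrature stated above. These
sizes reproduce the reference values to the tolerances asserted in
`tests/testthat/test-acceptance.R`; nothing in the package states an
empirical result that those runs do not themselves compute.

## Known limitations

* Population sizes: $N \le 6$ (independent) and $N \le 3$ (lumped, full
  counts); the recursive kernel cost grows quickly with $N R$.
* Local optimization only: the multistart grid targets the known structure
  of these landscapes but carries no global guarantee.
* Correlated input noise across neurons and partial/weighted lumping are
  out of scope.
* Eigenvalue exponent fits near a critical point inherit the
  finite-difference noise of the Hessian; the order-parameter fits are the
  numerically robust route.
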