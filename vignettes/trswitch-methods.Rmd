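---
title: "Inferring transcriptional regulation logic with trswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional regulation logic with trswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`trswitch` infers which subset of candidate transcription factors (TFs)
regulates a target gene, and the logic of that regulation, from time-series
mRNA expression observed in several experimental conditions. The target's
expression $M_k(t)$ in experiment $k$ follows a linear ODE with
first-order decay and a piecewise-constant transcription rate,

$$\frac{dM_k}{dt} = \tau_k(t) - \delta\, M_k(t), \qquad t \in [0, L_k],$$

where the rate $\tau_k(t)$ switches whenever a regulator's activity profile
$P_{\phi}(t)$ crosses its activation threshold $\rho_{\phi}$. A regulator is
active where $P_{\phi}(t) \ge \rho_{\phi}$ (the tie sits on the active
side; a crossing instant itself belongs to the following segment). For a
regulator set $\Phi = \{\phi_1, \dots, \phi_\nu\}$ the joint activation
state $\alpha(t) \in \{0,1\}^\nu$ is piecewise constant, and **each
observed state owns a single transcription rate shared across all
experiments and over time**. This cross-experiment consistency is the
source of identification: a candidate only helps if one threshold produces
switches that line up with the target's rate changes in every condition at
once. States that are never observed carry no parameter, which keeps the
parameterization minimal.

For fixed thresholds and $\delta$, the ODE solution is linear in the
initial conditions $M_k(0)$ and the per-state rates $\tau_{a_i}$: each
half-open segment $[l, r)$ of state $a_i$ contributes
$\tau_{a_i}\,(e^{-\delta(t - \min(r,t))} - e^{-\delta(t-l)})/\delta$ for
$t > l$. Segments are half-open so they tile each horizon exactly; the
closed-form factors are evaluated with non-positive exponents for
numerical stability.

## Likelihood and the plug-in fit

Observations are modelled as Gaussian around $M_k(t)$ with standard
deviation $\sigma_k(t) = \sigma_k\, w_k(t)^{-\psi_k}$, where $w_k(t)$ is a
fixed weight function (the reciprocal of a smoothed estimate of the
target's expression, floored at $10^{-6}$ of its maximum) and
$\psi_k \in [0,1]$ interpolates between homoscedastic ($\psi_k = 0$) and
noise proportional to expression level ($\psi_k = 1$). Replicates are
treated as conditionally independent observations sharing $M_k(t)$,
$\sigma_k$ and $\psi_k$; the initial condition is shared per experiment.

Rather than integrating over the linear coefficients, every likelihood
evaluation plugs in their weighted least squares estimates (effective
weights $w_k(t)^{2\psi_k}$), which makes a structure evaluation cheap
enough to run inside every MCMC step. The fit is unconstrained, as in the
underlying least-squares formulation; a negative fitted rate is reported
with a warning rather than constrained away. A rank-deficient design
(possible when a state's support precedes all observations) falls back to
the minimum-norm solution and is flagged.

## Priors

* Number of regulators: truncated Poisson($\lambda$), renormalized on
  $\{1, \dots, \nu_{\max}\}$, default $\lambda = 0.15$ and
  $\nu_{\max} = \min(N, 8)$. A small $\lambda$ is the main guard against
  overfitting, since the plug-in likelihood never penalizes extra states.
* Degradation rate: Gamma with mean 0.345 and sd 0.1543 per unit time
  (shape $= (\text{mean}/\text{sd})^2$, rate $= \text{mean}/\text{sd}^2$),
  matching an mRNA half-life of about two hours on an hourly time scale.
* Noise variances: scaled inverse-$\chi^2(n_0, s_0^2)$ with vague defaults
  $(0.001, 0.001)$, conjugate to the Gaussian likelihood.
* Variance exponents: uniform on $[0,1]$.
* Regulator sets: either uniform over size-$\nu$ subsets, or
  *informative* with per-TF weights proportional to the range of the
  smoothed profile across experiments (normalized via elementary symmetric
  polynomials so the marginal over $\nu$ stays exactly truncated-Poisson).
  Candidates whose expression barely moves make implausible switches.
  The weights deliberately use the *raw* range on the data's measurement
  scale: making them invariant to per-gene rescaling would erase exactly
  the dynamic-range information the prior is meant to encode, so
  comparability of scales across genes is a stated input requirement
  rather than something the package normalizes away.
* Thresholds: either uniform over the profile's range, or *informative*
  with density built from the profile's monotone runs — a segment
  traversing a level with slope $s$, inside a run sweeping a total span
  $S$, contributes mass $|s| \cdot S$ per unit level. Both factors encode
  that switches are caused by substantial changes: the slope factor
  prefers levels crossed quickly, and the span factor suppresses levels
  that are only traversed by small (noise-scale) wiggles of an otherwise
  flat stretch. For a linear ramp the density is uniform over the range;
  for a flat profile with one steep jump it concentrates on the jump. The
  discretized density (256 cells) is mixed with a 1% uniform component so
  no admissible threshold has zero prior mass.

## The reversible-jump sampler

Each iteration performs, in order:

1. a structure move — **M** (truncated-normal random walk on one
   threshold, sd `sigma_rho` × range, truncated to the range so no
   regulator can become globally redundant), **S** (swap a regulator for
   an excluded one, new threshold uniform on its range), **B**/**D**
   (birth/death) — accepted with the full Metropolis–Hastings–Green ratio
   of prior, plug-in likelihood and proposal terms. Birth and death
   probabilities follow $\pi_B(\nu) = c\min\{1, \pi(\nu+1)/\pi(\nu)\}$,
   $\pi_D(\nu) = c\min\{1, \pi(\nu-1)/\pi(\nu)\}$ with $c$ maximized
   subject to $\pi_B + \pi_D \le \pi_{BD}$, which makes the pair satisfy
   the balance equation; the Poisson prior ratio then cancels against the
   schedule ratio in the acceptance probability, but the implementation
   computes the full ratio so the cancellation is emergent rather than
   assumed.
2. a Gaussian random walk on $\delta$ (default sd 0.05), with the design
   matrix rebuilt since it depends on $\delta$; non-positive proposals are
   rejected outright.
3. conjugate draws of each $\sigma_k^2$ from scaled
   inverse-$\chi^2(n_0 + n_k,\ [n_0 s_0^2 + \mathrm{RSS}_k^w]/(n_0+n_k))$.
4. draws of each $\psi_k$ from its full conditional evaluated on a fixed
   grid of 201 points (holding the current residuals and $\sigma_k$
   fixed), sampled by cell with a uniform jitter within the cell; the
   weighted fit is then refreshed once for the new exponents.

Defaults: 10% burn-in, thinning to at most $10^4$ retained draws,
`sigma_rho = 0.1`, $\pi_{BD} = 0.5$, an even split of the remaining
probability between M and S moves. Proposal scales and the schedule
constants are configurable; the defaults were chosen for acceptance rates
in the 0.2–0.6 range on the benchmark studies. A `flat_likelihood` switch
turns the sampler into a prior sampler (used to verify that the chain
reproduces its own prior), and `fix_delta` / `fix_psi` hold those
parameters for calibration checks against exhaustive enumeration.

## Preprocessing

Candidate profiles are continuous proxies for TF activity built from the
observed mRNA: a cross-validated (GCV) smoothing spline per experiment,
pooling replicates, with the equivalent degrees of freedom capped at 60%
of the number of distinct time points — GCV is prone to undersmoothing
short replicated series, and the resulting wiggle would propagate into
spurious threshold crossings. The smoothed curve is optionally transformed
by an affine map, a time delay,
or a first-order translation ODE when protein dynamics should be modelled
explicitly. The default proxy is the smoothed mRNA curve itself, which is
how expression-profiling applications use the method. A wild bootstrap
(two-point Mammen weights) provides pointwise envelopes around each
smoothed profile as a diagnostic; inference conditions on the
point-estimate curves, and sensitivity to profile uncertainty is assessed
by rerunning on bootstrap replicates rather than by propagating the
envelope into the posterior.

## The benchmark generators

Two seeded generators reproduce the structure of the published simulation
studies this method was demonstrated on; their exact ODE constants are not
public, so the generators realize the *described* qualitative structure
with constants fixed once, documented here.

**Repressed activation.** A target and six candidate TFs in two
experiments over 10 h, sampled at irregular spacings (uniform in
0.5–1.5 h) shared by four replicates; profiles are $\Omega h(t)$ with
$\Omega = 10^3$ plus i.i.d. Gaussian noise of sd $\Omega/20$. The shapes
$h(t)$ are logistic transitions (rate 2/h) crossing mid-range at: f1 up at
2 h (condition 1) and down at 7 h (condition 2); f2 up at 6 h / 3 h. The
target's rate law is a steep Hill gate (exponent 40, mid-point at
mid-range) in f1 times a mirrored gate in f2, scaled so the baseline and
activated expression levels are 100 and 750: transcription is high only
while f1 is active and f2 is not — f2 represses f1's activation.
Confounders: f3 = f2's condition-2 shape in both conditions; f4 constant
low/high across conditions (the only deliberately flat profiles, as
specified); f5 = the mirror image of f2, observed with 2.5× the
measurement noise so its smoothed profile is a less reliable switch; f6 =
f1's shape compressed to 40% of the range. The switches act on
first-order protein transforms of the mRNA shapes (turnover 1.5/h, a
~28 min protein half-life) while only mRNA is observed; this mild,
realistic protein/mRNA mismatch penalizes regulators whose transitions run
in opposite directions across conditions (the threshold shift that absorbs
the translation lag on a rising profile is inconsistent with the shift
needed on a falling one) and is part of what separates f2 from its mirror
image f5.

**SOC1 flowering network.** The target SOC1 plus eight network genes in
four conditions over 10 days (same sampling and noise rules, rates per
day; protein-filter turnover 4/day). Five regulators: the Hill-gated
activators FT and AGL24 (OR-type), the repressors SVP and FLC, and SOC1
itself through a positive auto-regulatory term with mid-point at 0.18 of
the amplitude — the target is its own candidate regulator, and the low
auto mid-point makes the auto-switch fire visibly *between* the other
switches rather than coincide with them. Conditions differ in which
regulators switch and when, so each true threshold is pinned by at least
one condition: FLC's fall matters in condition 2, FT alone drives
condition 3, condition 4 stays repressed under high FLC throughout, and
SVP *returns* late in condition 1 so the target rises and then falls —
without that fall the target's own monotone profile could self-explain
every rise through auto-thresholds alone. Each non-regulator (FD, AP1,
LFY, CO) has exactly one full transition, placed in a window where the
target's rate is constant, and only noise-scale one-sided drifts
elsewhere. Both exact flats and rich multi-condition dynamics were avoided
deliberately: the smoothed proxy of a flat profile wiggles at the noise
scale, so thresholds inside that band place switches almost freely in
time, while a distractor with transitions in several conditions donates
several adjustable switches — either way such a candidate absorbs residual
structure it has no causal relation to, which the plug-in likelihood never
penalizes. SOC1 chains use a 20% burn-in: the climb from the one-regulator
initial state to the five-regulator mode is slow in the nine-candidate
space.

`simulate_from_trs()` generates data *exactly* from the switch model for
arbitrary structures and is the gold standard for parameter-recovery
checks.

What the generators do not emulate: correlated measurement errors,
between-replicate biological variation, platform or batch effects, and
cross-platform scale differences (profiles must arrive on comparable
scales). Passing the benchmark checks therefore demonstrates correctness
of the machinery under the stated noise model, not robustness to real
microarray artefacts.

## Numerical choices

* Profiles are evaluated on 201-point grids per experiment; crossings are
  found analytically on each linear segment, so a threshold's switch
  times are exact for the piecewise-linear interpolant.
* Breakpoints closer than $10^{-10}$ are merged; zero-length segments are
  dropped.
* The weighted least squares solve uses a pivoted QR; rank deficiency
  falls back to an SVD minimum-norm solution.
* The ODE design factors are computed as differences of
  $e^{-\delta \cdot (\cdot)}$ with non-positive exponents only.
* Degenerate inputs reject early: thresholds outside a profile's range
  ("redundant regulator"), non-positive $\delta$ or $\sigma$, fewer than
  four time points per experiment for smoothing.

## Problem sizes in the test suite

The automated checks run at reduced sizes chosen to keep the full suite
fast while leaving the conclusions unchanged: oracle comparisons use 100
random ODE instances and 50 random regression designs; prior-recovery uses
$10^5$ flat-likelihood iterations; the enumeration calibration uses two
candidates with 20 threshold cells and a 60k-iteration chain with the
degradation rate, noise scale and variance exponents held fixed; recovery
of the repressed-activation pair uses ten seeds at 100k iterations; the
benchmark posterior checks use 80k (repressed activation) and 100k (SOC1)
iterations. The `scripts/acceptance.R` driver reruns the two studies at
200k/100k iterations, the scale at which the posterior summaries
stabilize.

## Known limitations

* The plug-in likelihood has no built-in dimension penalty; model-size
  control rests entirely on the Poisson prior and the informative set and
  threshold priors. With uniform priors and a generous $\lambda$, extra
  regulators that absorb replicate-level noise clusters are readily
  accepted — consistent with the published observation that small
  $\lambda$ and informative priors are needed for robust results.
* One target at a time; no joint network inference.
* Deterministic population-average ODE only; no stochastic kinetics.
* Thresholds are assumed constant across experiments, which is the
  method's core consistency assumption and also its main vulnerability if
  conditions rescale expression differently.
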