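---
title: "Dynamic computational phenotyping: models, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic computational phenotyping: models, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenodyn estimates *computational phenotypes* — vectors of cognitive-model
parameters fitted per person and per week — from a longitudinal battery of
seven behavioural tasks, and asks where their week-to-week variability comes
from: practice, affective state (valence and arousal), or residual noise.
This vignette is the package's own account of the models, the estimation
choices, and what the validation suite does and does not establish.

## The task models

Each weekly session of each task is scored by a trial-level likelihood with
a small set of free parameters; the same generative process drives the
matched simulator, so simulation and scoring can never drift apart.

* **Go/No-go** (`gng`, 3 blocks x 80 trials): Rescorla-Wagner values
  `Q(a, s)` and a Pavlovian stimulus value `V(s)` start at zero per block
  and update with learning rate $\varepsilon$ toward the effective outcome.
  Rewards and punishments count $\pm\rho_{rew/pun}$; neutral outcomes are
  context-coded, $-\rho_{neut}$ in win conditions and $+\rho_{neut}$ in
  avoid conditions. Action weights are $W(go) = Q(go,s) + b + \pi V(s)$ and
  $W(nogo) = Q(nogo,s)$; the Go probability is
  $(1-\xi)\,\sigma(W(go)-W(nogo)) + \xi/2$ with lapse rate $\xi$. Only the
  taken action's $Q$ updates; $V(s)$ updates every trial of stimulus $s$
  (Pavlovian value is stimulus-bound). Outcomes follow the 80/20
  contingency of the design.
* **Change detection** (`cd`, 5 blocks x 40 trials, set sizes 3/4/6/8 plus
  a multiple-target block): each item's encoded colour difference is
  $d_i + \eta$, $\eta \sim N(0, 2\sigma(N)^2)$, flagged when it exceeds
  $\theta(N)$; "different" iff any item is flagged. Both $\sigma$ and
  $\theta$ rise linearly with set size. Hue differences are circular
  distances in degrees treated as linear magnitudes inside the Gaussian
  rule; the multiple-target block uses the same per-item rule.
* **Random dot motion** (`rdm`, 4 x 96 trials): an unbiased drift
  diffusion model, drift $\delta c$ linear in coherence
  $c \in \{.05,.10,.35,.50\}$, boundary $\alpha$, non-decision time
  $\tau$, start $z=\alpha/2$, unit diffusion. Densities use the dual
  small-/large-time series with an accuracy-optimal switching rule and a
  truncation target of $10^{-7}$. Trials without a response inside 1.5 s,
  or with RT $\le \tau$, are excluded from the likelihood and counted.
* **Lottery ticket** (`lt`, 3 x 10 trials at EV scales ~\$2/\$50/\$200):
  $U = \sum_j p_j x_j^{\rho}$ and a softmax with inverse temperature
  $\beta$; certain-win trials are removed before modelling.
* **Intertemporal choice** (`itc`, 27-item menu): hyperbolic value
  $A/(1+kD)$ with delays in days and a softmax.
* **Two-armed bandit** (`tab`, 30 x 10 trials): a Kalman filter per arm
  (block-reset) yields the value difference $V$, relative uncertainty
  $RU$, and total uncertainty $TU$; choice is
  $\Phi(w_V V + w_{RU} RU + w_{sTU}\,\mathrm{sign}(V)/TU)$ with
  $\mathrm{sign}(0)=0$. The recursion is parameter-free given the data, so
  the likelihood is an ordinary probit in precomputed regressors. The
  safe-arm observation variance is $10^{-6}$, a numerical stand-in for a
  deterministic arm; prior mean/variance and the risky observation
  variance are design configuration, as are the block-level reward
  distributions.
* **Numerosity comparison** (`nc`, 160 trials): noisy count estimates
  $N(a, a^2w^2)$ give
  $p(\text{choose } 1) = \Phi\big((a_1-a_2)/(w\sqrt{a_1^2+a_2^2})\big)$.

RTs are milliseconds in files and seconds inside likelihoods. Missing
responses stay in the files, are excluded from likelihoods, and are
counted in each likelihood's audit fields.

## The hierarchical statistical models

Session-level phenotypes live in an unconstrained space (log for positive
parameters, logit for unit-interval ones, identity otherwise) and the
hierarchy is applied independently to each scalar parameter — each has its
own group mean, spread and session noise.

* **Independent**: $y^s_t \sim N(\mu^s, \sigma)$,
  $\mu^s \sim N(\mu^g, \eta_g)$, with $\mu^g \sim N(0,1)$ and half-normal
  (0, 1) priors on $\sigma$ and $\eta_g$.
* **Reduced**: no participant level; $y^s_t \sim N(\mu^g, \sigma)$.
* **Dynamic**: the session mean gains a saturating power-law practice term
  and state terms,
  $\mu^s + \delta^s_p (1 - t^{-b^s}) + \delta^s_v v^s_t + \delta^s_a a^s_t$.
  Each effect magnitude is a fixed population fraction of the personal
  baseline, $\delta^s_i = \delta_i \mu^s$ with
  $\delta_i = 2\Phi(\delta_i^{prior})-1 \in (-1,1)$ and a standard-normal
  prior on $\delta_i^{prior}$. The time index $t$ is the calendar week, so
  the practice term is exactly zero in week 1; missing weeks drop out of
  the likelihood but observed weeks keep their calendar index. The
  exponent is constrained to $e^{-2} < b^s < e$ to stop a flattening curve
  from trading off against the baseline; we parameterize
  $b^s = \exp(u^s)$ with $u^s$ mapped to $(-2, 1)$ through a scaled logit
  of a raw score that is partially pooled with a normal population prior —
  this respects the bound while keeping the sampling geometry smooth.

A consequence worth knowing: because $\delta^s_i$ scales with $\mu^s$,
dynamic effects vanish for participants whose baseline sits at zero in the
unconstrained space. This is a property of the model, documented rather
than patched; it mainly matters for sign-free parameters such as the
bandit weights.

## Estimation

Fits use an adaptive Hamiltonian Monte Carlo sampler written for this
package: dual-averaging step-size adaptation toward 0.8 acceptance, a
diagonal mass matrix estimated from the second half of warmup, a jittered
number of leapfrog steps, and rejected transitions with large Hamiltonian
error counted as divergences. The chain contract mirrors common practice
for these models: 4 chains, 1,000 warmup and 1,000 kept iterations,
hyper-parameters initialized at zero in the unconstrained space; split
R-hat, effective sample size and the divergence count gate phenotype
extraction (threshold R-hat 1.01, configurable).

Two estimation paths share this machinery:

* `method = "joint"` samples the latent session phenotypes together with
  the hierarchy against the trial likelihoods (analytic gradients for all
  tasks except the diffusion model, which uses per-session finite
  differences). Latent session values are initialized at their per-session
  MAP rather than zero so the diffusion non-decision time starts inside
  its support.
* `method = "two_stage"` (default) first computes a per-session MAP with a
  weak $N(0, 2.5)$ regularizer in the unconstrained space and a Laplace
  standard error, then samples the hierarchy with the session likelihood
  replaced by that Gaussian summary, the latent value integrated out
  analytically. Session-level posteriors are recovered from the conjugate
  conditional. This is the approximation used for cohort-scale runs; on
  small problems where both are feasible the two paths agree within
  Monte Carlo error (see `test-fit.R`), and the joint path remains the
  reference semantics.

## Survey states

Survey responses (35 numeric items; the free-text item is excluded) are
arranged one row per observed (participant, week, day) session, z-scored
per item across available rows, rows with missing items dropped, and PCA
run on the result. The first two components are read as affective valence
and arousal; components are oriented by the mean loading of designated
positive-emotion / arousal items (or, absent that information, so the
largest-magnitude loading is positive — deterministic either way). Scores
are averaged over the days of each week, missing weeks are linearly
interpolated per participant *after* the PCA, and each participant's
series is affinely mapped so its observed minimum and maximum hit $-1$ and
$+1$ (constant series map to 0) before entering the dynamic model.

## Psychometric analytics

* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measurement — from the ANOVA mean squares of a complete
  participants x sessions matrix of posterior means, with a 1,000-sample
  bootstrap over participants. Complete-case filtering is the default;
  the `nmax` variant instead truncates every participant to their first
  $N_{max}$ observed sessions. Bootstrap resamples that draw a single
  participant repeatedly carry no between-participant information and are
  redrawn.
* **Relative contribution**: per participant, the posterior-mean time
  series of each dynamic term (practice, valence, arousal, noise) in the
  unconstrained space; a term's contribution is its s.d. across sessions
  divided by the summed s.d.s. The baseline term is constant over time
  (s.d. 0), so including it would change nothing; it is excluded.
* **Probability of direction**: the percentage of posterior mass sharing
  the sign of the median, labelled uncertain / possibly / likely /
  probably / certainly existing at 95 / 97 / 99 / 99.9.
* **Practice curves**: behavioural series are fit with
  $\hat y(t) = A - B\,t^{-C}$ (the saturating form mirroring the dynamic
  model's practice term), profiled over $C$ since the model is linear in
  $(A, B)$ given $C$; adjusted $R^2$ uses 3 fitted parameters. The
  permutation test refits under random session orders with add-one
  smoothing, $p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$, avoiding
  zero p-values.

## The synthetic cohort

The generator *is* the study design: 90 participants x 12 weekly sessions
by default, the printed per-session trial counts (gng 240, cd 200, rdm
384, lt 30, itc 27, tab 300, nc 160), 80/20 Go/No-go contingencies, the
printed lottery ticket shape at three EV scales. Ground-truth trajectories
are composed exactly as the dynamic model writes them (baseline +
practice + valence + arousal + noise, stored separately so the
decomposition is testable to machine precision) and task data are then
simulated from the constrained values.

Values the design leaves open were chosen once, on field-typical
magnitudes, and not revisited: group means such as a learning rate near
0.2, a lapse rate near 0.1, a Weber fraction near 0.22, a discount rate
near 0.02/day; between-participant spreads of 0.12-0.8 and session noise
of 0.08-0.3 in the unconstrained space; population effect fractions
$\delta_p = 0.3$, $\delta_v = 0.1$, $\delta_a = 0$ mirroring the
qualitative pattern that practice effects are pervasive, valence effects
occasional, and arousal effects rare. Latent states evolve as AR(1)
series (coefficient 0.6) to emulate week-to-week mood persistence — the
fitted model does not assume this; it is generator-only structure. Survey
items load on the two latent factors with valence carrying clearly more
item variance than arousal, so the leading component is the valence axis;
responses are binned to a 1..7 scale.

What passing recovery tests shows — and what it does not: the synthetic
cohort has no task-switching artefacts, no RT autocorrelation, no dropout
economics, and state effects that really are linear in the normalized
latents. Recovery on it demonstrates the estimation machinery is
self-consistent at the study's design size, not that real behaviour obeys
these forms.

## Problem sizes and numerical choices

Desk-scale runs in the test suite and acceptance script use 20
participants x 8 weeks with 2 chains x 500/500 (the full 90 x 12 with
4 x 1000/1000 is a configuration change); the survey-PCA checks use
30 x 8, where the sample correlation between the two latent series is
small enough for the orthogonal component scores to separate them. The
Euler oracle for the diffusion model uses dt = 0.2 ms, keeping the
$O(\sqrt{dt})$ first-passage bias well under the 10 ms scale of the
comparison. Probabilities inside likelihoods are clamped to
$[10^{-12}, 1-10^{-12}]$; per-evaluation truncation error of the Wiener
series is $10^{-7}$; transform round-trips are exact to $10^{-12}$.

Identification is not uniform across the phenotype. Single-session data
constrain the change-detection intercepts and slopes jointly (they are
partly confounded along the set-size line), the Go/No-go biases are
weakly determined by 240 trials, and the 30-trial lottery sessions carry
little information about $\beta$; the hierarchy is what makes their
estimates usable. The validation bars (correlation at least 0.8 for
well-identified parameters, 0.5 for weakly identified ones; 80% power for
the practice-effect detection) are implementer-set thresholds recorded in
`identifiability_bars()`, not claims imported from elsewhere.

## Known limitations

The gap-counting rule for inclusion counts runs of missing weeks between
a participant's first and last observed week; an `edge_gaps` switch
provides the stricter reading that also counts leading/trailing runs.
The two-stage path propagates session information through a Gaussian
Laplace summary, which can understate skew in small-trial sessions.
Constrained-space point estimates average the transformed conditional
draws, so they are posterior means in the constrained space up to Monte
Carlo error. The CLI is a thin file-based wrapper; anything serious
should use the R API directly.
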