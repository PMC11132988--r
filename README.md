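# phenodyn

Dynamic computational phenotyping of cognitive task batteries in R.

A *computational phenotype* is the vector of cognitive-model parameters —
learning rates, decision thresholds, risk attitudes, Weber fractions —
fitted to one person's behaviour. Measured weekly over months, these
parameters drift, and the central question this package addresses is
*why*: how much of the week-to-week variability is practice, how much
tracks affective state (valence and arousal from daily self-reports), and
how much is residual noise. phenodyn is written for computational
cognitive scientists and psychometricians who run (or simulate)
longitudinal task batteries and need the full pipeline: trial-level task
models, hierarchical Bayesian estimation, and stability analytics.

## What is inside

**Seven task models** (likelihood + matched simulator, sharing one
generative process): a Pavlovian Go/No-go reinforcement-learning model
with context-coded neutral outcomes; a maximum-absolute-difference colour
change-detection model with set-size-dependent noise and threshold; a
drift diffusion model for random dot motion (dual-series Wiener
first-passage density); risk-sensitive lottery choice
(`U = sum p x^rho` with softmax); hyperbolic intertemporal choice
(`A/(1+kD)`); a Kalman-filter two-armed bandit with a probit policy over
value difference, relative uncertainty and signed total uncertainty; and
Weber-fraction numerosity comparison.

**Three hierarchical models** over the weekly phenotype `y_t^s`
(unconstrained space, one scalar hierarchy per parameter):

- *independent*: `y_t^s ~ N(mu^s, sigma)`, `mu^s ~ N(mu^g, eta_g)`;
- *reduced*: `y_t^s ~ N(mu^g, sigma)` (no participant level);
- *dynamic*: `y_t^s ~ N(mu^s + delta_p^s (1 - t^(-b^s)) +
  delta_v^s v_t^s + delta_a^s a_t^s, sigma)` — a saturating power-law
  practice term plus valence/arousal state terms, each effect a population
  fraction of the personal baseline (`delta_i^s = delta_i mu^s`,
  `delta_i = 2 Phi(delta_i^prior) - 1`), with the practice exponent
  constrained to `(e^-2, e)`.

Fitting uses a package-authored adaptive Hamiltonian Monte Carlo sampler
(4 chains, 1,000 warmup + 1,000 kept by default; split R-hat, ESS and
divergence gates), either jointly against the trial likelihoods or via a
fast two-stage approximation (per-session MAP + Laplace summary).

**Analytics**: bootstrapped ICC(2,1) (complete-case and first-N_max
variants), an ICC ceiling experiment with time-constant simulated agents,
relative contributions of practice/valence/arousal/noise, probability of
direction with graded labels, and power-law practice-curve fits with
session-order permutation tests. **Survey module**: z-scoring + PCA to
valence/arousal scores, week aggregation, post-PCA interpolation,
within-participant normalization to [-1, 1]. **Synthetic cohort
generator**: the full 90-participant x 12-week design with ground truth
retained, used throughout the validation suite.

## Worked example

```r
library(phenodyn)
library(dplyr)

# a synthetic study: 12 participants, 8 weekly sessions, numerosity task,
# with a practice effect worth 30% of each personal baseline
grp <- default_group_spec() |> filter(task == "nc")
cfg <- cohort_config(n_participants = 12, weeks = 8, tasks = "nc",
                     group = grp)
cohort <- generate_cohort(cfg, seed = 1)

# survey -> affective states
states <- cohort$survey |>
  compute_state_components() |>
  normalize_states() |>
  select(participant_id, week, valence, arousal)

# dynamic hierarchical fit (desk-scale chains)
fit <- fit_model(cohort$trials$nc, "nc", variant = "dynamic",
                 states = states, chains = 2,
                 iter_warmup = 400, iter_sampling = 400, seed = 1)
fit
#> <phenodyn_fit> task: nc  variant: dynamic  method: two_stage
#>   participants: 12  sessions: 96  chains: 2 x( 400 + 400 )
#>   max split R-hat: 1.0395  divergences: 0

tidy(fit) |> filter(term == "delta_p")
#> # A tibble: 1 x 6
#>   parameter term    estimate std.error conf.low conf.high
#>   <chr>     <chr>      <dbl>     <dbl>    <dbl>     <dbl>
#> 1 w         delta_p    0.530     0.197    0.257     0.921

fit$draws |> filter(quantity == "d_p") |> pull(value) |>
  probability_of_direction()
#> # A tibble: 1 x 3
#>      pd median_sign label
#>   <dbl>       <dbl> <chr>
#> 1   100           1 certainly existing
```

The generating practice fraction was 0.3. The fit detects the injected
practice effect with a probability of direction of 100 ("certainly
existing"); its posterior mean of 0.53 carries a wide 90% interval
(0.26-0.92) that covers the truth — `delta_p` is the *asymptotic*
practice change, extrapolated beyond the 8 observed weeks, so its
magnitude is diffuse at 12 participants even when its direction is
certain. Stability of the weekly estimates is one call away:

```r
ph <- to_phenotype_matrix(fit, space = "unconstrained", override = TRUE)
bootstrap_icc(phenotype_wide(ph, "w"), n_boot = 1000, seed = 1)
#> ICC(2,1) = 0.887 | bootstrap median 0.877 IQR 0.046 | n = 12 k = 8 ( complete_case )
```

A thin command-line wrapper covering simulate / states / fit / analyze /
validate lives at `inst/cli/phenodyn.R`
(`Rscript inst/cli/phenodyn.R simulate --out data/ --seed 7 ...`).

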