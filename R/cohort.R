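#' Reference group-level distribution of the computational phenotype
#'
#' One row per task parameter: the group mean `mu_g` (unconstrained
#' space), the between-participant s.d. `eta_g`, the session-level s.d.
#' `sigma`, and the population fractions of the dynamic effects
#' (`delta_p` practice, `delta_v` valence, `delta_a` arousal, each in
#' (-1, 1) and applied as `delta_i^s = delta_i * mu^s`). Values are
#' field-typical magnitudes chosen once for the synthetic study (see the
#' methods vignette); override any row via the `group` argument of the
#' generators.
#'
#' @return Tibble with columns `task`, `parameter`, `mu_g`, `eta_g`,
#'   `sigma`, `delta_p`, `delta_v`, `delta_a`.
#' @export
default_group_spec <- function() {
  spec <- dplyr::tribble(
    ~task, ~parameter, ~mu_g, ~eta_g, ~sigma,
    "gng", "b",            0.20, 0.40, 0.25,
    "gng", "pi",           0.30, 0.40, 0.25,
    "gng", "eps",         -1.39, 0.40, 0.25,
    "gng", "rho_rp",       0.69, 0.40, 0.25,
    "gng", "rho_neut",     0.00, 0.40, 0.25,
    "gng", "xi",          -2.20, 0.40, 0.25,
    "cd",  "sigma0",       1.79, 0.30, 0.20,
    "cd",  "theta0",       3.81, 0.30, 0.15,
    "cd",  "sigma_slope",  0.41, 0.30, 0.20,
    "cd",  "theta_slope", -0.22, 0.30, 0.20,
    "rdm", "alpha",        0.41, 0.30, 0.15,
    "rdm", "tau",         -1.20, 0.20, 0.10,
    "rdm", "delta",        1.79, 0.35, 0.15,
    "lt",  "rho_risk",    -0.16, 0.25, 0.15,
    "lt",  "beta",        -1.20, 0.50, 0.30,
    "itc", "k",           -3.91, 0.80, 0.30,
    "itc", "beta",        -0.69, 0.50, 0.30,
    "tab", "w_V",          0.15, 0.12, 0.08,
    "tab", "w_RU",         0.20, 0.15, 0.10,
    "tab", "w_sTU",        0.50, 0.30, 0.20,
    "nc",  "w",           -1.51, 0.30, 0.15)
  spec$delta_p <- 0.30
  spec$delta_v <- 0.10
  spec$delta_a <- 0.00
  spec
}

#' Configuration of a synthetic longitudinal cohort
#'
#' The default emulates the full study design: 90 participants, 12 weekly
#' sessions, all seven tasks, no missingness; desk-scale runs typically
#' use 20 participants x 8 weeks. Latent affective states evolve as AR(1)
#' series per participant (week-to-week mood persistence), which is
#' generator-only structure.
#'
#' @param n_participants Number of participants (default 90).
#' @param weeks Number of weekly sessions (default 12).
#' @param tasks Tasks to simulate (default all seven).
#' @param missingness Per participant-week-task probability of a skipped
#'   session (default 0).
#' @param group Group spec tibble (default [default_group_spec()]).
#' @param b_z_mu,b_z_sd Population location/spread of the raw practice
#'   exponent score (the exponent is `b = exp(-2 + 3 logistic(z))`).
#' @param state_ar AR(1) coefficient of the latent state series.
#' @param survey_days Survey days per week (default 3).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 90, weeks = 12,
                          tasks = task_codes(), missingness = 0,
                          group = default_group_spec(),
                          b_z_mu = 0, b_z_sd = 0.5,
                          state_ar = 0.6, survey_days = 3) {
  stopifnot(n_participants >= 1, weeks >= 1, missingness >= 0, missingness < 1)
  if (any(abs(group$delta_p) >= 1) || any(abs(group$delta_v) >= 1) ||
      any(abs(group$delta_a) >= 1)) {
    abort("population effect fractions delta_i must lie in (-1, 1)")
  }
  structure(list(n_participants = n_participants, weeks = weeks,
                 tasks = tasks, missingness = missingness, group = group,
                 b_z_mu = b_z_mu, b_z_sd = b_z_sd, state_ar = state_ar,
                 survey_days = survey_days),
            class = "cohort_config")
}

#' Generate ground-truth phenotype trajectories
#'
#' Draws participant baselines `mu^s ~ N(mu^g, eta_g)` per parameter,
#' forms the dynamic effect magnitudes `delta_i^s = delta_i * mu^s`, draws
#' per-participant practice exponents and latent AR(1) valence/arousal
#' series (normalized to [-1, 1] within participant), and composes the
#' session-level phenotype as the sum of the five terms of the dynamic
#' model: baseline + practice + valence + arousal + Normal(0, sigma)
#' noise, in the unconstrained space. All terms are stored separately so
#' that the realized trajectory equals their sum exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `cohort_truth` list: `config`, `participants` (per-
#'   participant parameter table), `states` (latent weekly states),
#'   `trajectories` (per participant x week x parameter terms and realized
#'   `y`), `mask` (observed participant x week x task grid).
#' @export
generate_trajectories <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(child_seed(seed, "trajectories"))
  ids <- sprintf("p%03d", seq_len(config$n_participants))
  grp <- filter(config$group, .data$task %in% config$tasks)

  # latent AR(1) states, normalized within participant to [-1, 1]
  states <- purrr::map_dfr(ids, function(id) {
    v <- ar1_series(config$weeks, config$state_ar)
    a <- ar1_series(config$weeks, config$state_ar)
    tibble(participant_id = id, week = seq_len(config$weeks),
           valence = minmax_pm1(v), arousal = minmax_pm1(a),
           valence_latent = v, arousal_latent = a)
  })

  participants <- purrr::map_dfr(ids, function(id) {
    grp |>
      mutate(participant_id = id,
             mu_s = rnorm(dplyr::n(), .data$mu_g, .data$eta_g),
             z_s = rnorm(dplyr::n(), config$b_z_mu, config$b_z_sd)) |>
      mutate(b_s = b_of_z(.data$z_s),
             delta_p_s = .data$delta_p * .data$mu_s,
             delta_v_s = .data$delta_v * .data$mu_s,
             delta_a_s = .data$delta_a * .data$mu_s) |>
      select("participant_id", "task", "parameter", "mu_s", "z_s", "b_s",
             "delta_p_s", "delta_v_s", "delta_a_s", "sigma")
  })

  trajectories <- participants |>
    tidyr::expand_grid(week = seq_len(config$weeks)) |>
    left_join(select(states, "participant_id", "week", "valence", "arousal"),
              by = c("participant_id", "week")) |>
    mutate(
      practice = .data$delta_p_s * (1 - .data$week^(-.data$b_s)),
      valence_term = .data$delta_v_s * .data$valence,
      arousal_term = .data$delta_a_s * .data$arousal,
      noise = rnorm(dplyr::n(), 0, .data$sigma),
      y = .data$mu_s + .data$practice + .data$valence_term +
        .data$arousal_term + .data$noise) |>
    select("participant_id", "task", "parameter", "week", "mu_s",
           "practice", "valence_term", "arousal_term", "noise", "y")

  mask <- tidyr::expand_grid(participant_id = ids,
                          week = seq_len(config$weeks),
                          task = config$tasks) |>
    mutate(observed = runif(dplyr::n()) >= config$missingness)

  structure(list(config = config, participants = participants,
                 states = states, trajectories = trajectories, mask = mask,
                 seed = seed),
            class = "cohort_truth")
}

ar1_series <- function(n, rho) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in seq_len(n - 1)) {
    x[t + 1] <- rho * x[t] + rnorm(1, 0, sqrt(1 - rho^2))
  }
  x
}

#' Default survey item specification
#'
#' 35 numeric items (ids 1..36 without the free-text item 34) loading on
#' the two latent affective factors: positive- and negative-valence items,
#' arousal items, and weakly loading filler items, each with ordinal
#' 1..7 binning. Attributes `valence_items` / `arousal_items` give the
#' ids used to orient the PCA components.
#'
#' @param noise_sd Item-level Gaussian noise s.d. (default 0.4).
#' @return Tibble: `item_id`, `load_v`, `load_a`, `noise_sd`.
#' @export
default_item_spec <- function(noise_sd = 0.4) {
  ids <- setdiff(1:36, 34)
  spec <- tibble(item_id = ids, load_v = 0, load_a = 0, noise_sd = noise_sd)
  pos <- ids[1:6]; neg <- ids[7:12]; aro <- ids[13:22]
  spec$load_v[spec$item_id %in% pos] <- 1
  spec$load_v[spec$item_id %in% neg] <- -1
  # valence carries clearly more item variance than arousal, so the leading
  # component is the valence axis
  spec$load_a[spec$item_id %in% aro] <- 0.8
  # affect items also pick up some intensity, mirroring arousal loadings
  spec$load_a[spec$item_id %in% c(pos, neg)] <- 0.15
  filler <- setdiff(ids, c(pos, neg, aro))
  spec$load_v[spec$item_id %in% filler] <- 0.1
  structure(spec, valence_items = pos, arousal_items = aro)
}

#' Generate survey item responses from the latent affective factors
#'
#' Item responses are `load_v * valence + load_a * arousal + noise`,
#' binned to a 1..7 ordinal scale, for each survey day of each observed
#' week (daily latents jitter around the weekly latent).
#'
#' @param truth A `cohort_truth`.
#' @param item_spec Item specification (default [default_item_spec()]).
#' @param seed Integer seed.
#' @param day_jitter_sd Day-level jitter of the latent states.
#' @param bin Bin responses to the 1..7 ordinal scale (default). `FALSE`
#'   keeps continuous responses, in which case zero-noise pure-loading
#'   items reproduce the latents exactly up to affine maps.
#' @return Survey tibble (`participant_id`, `week`, `day`, `item_id`,
#'   `response`).
#' @export
generate_survey_items <- function(truth, item_spec = default_item_spec(),
                                  seed = 1, day_jitter_sd = 0.2, bin = TRUE) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (all(item_spec$load_v == 0 & item_spec$load_a == 0)) {
    abort("degenerate item spec: all loadings zero")
  }
  set.seed(child_seed(seed, "survey"))
  days <- seq_len(truth$config$survey_days)
  grid <- tidyr::expand_grid(
    select(truth$states, "participant_id", "week",
           v = "valence_latent", a = "arousal_latent"),
    day = days)
  grid$v_day <- grid$v + rnorm(nrow(grid), 0, day_jitter_sd)
  grid$a_day <- grid$a + rnorm(nrow(grid), 0, day_jitter_sd)
  out <- tidyr::expand_grid(grid, item_spec)
  raw <- out$load_v * out$v_day + out$load_a * out$a_day +
    rnorm(nrow(out), 0, out$noise_sd)
  out$response <- if (bin) pmin(pmax(round(4 + 1.5 * raw), 1), 7) else raw
  out |>
    select("participant_id", "week", "day", "item_id", "response") |>
    arrange(.data$participant_id, .data$week, .data$day, .data$item_id)
}

#' Generate a full synthetic cohort
#'
#' Composes [generate_trajectories()], per-session task simulation via
#' [simulate_task()] at the constrained trajectory values, and
#' [generate_survey_items()], honouring the configured missingness mask.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; equal seeds give identical cohorts.
#' @return List with `trials` (named list of per-task trial tibbles),
#'   `survey`, and `truth` (the `cohort_truth` with all generator state).
#' @export
generate_cohort <- function(config, seed = 1) {
  truth <- generate_trajectories(config, seed)
  info_all <- lapply(config$tasks, task_params)
  names(info_all) <- config$tasks
  trials <- lapply(config$tasks, function(tk) {
    info <- info_all[[tk]]
    tj <- filter(truth$trajectories, .data$task == tk)
    msk <- filter(truth$mask, .data$task == tk, .data$observed)
    rows <- purrr::pmap(list(msk$participant_id, msk$week), function(id, wk) {
      yy <- tj[tj$participant_id == id & tj$week == wk, ]
      th <- setNames(yy$y[match(info$parameter, yy$parameter)], info$parameter)
      simulate_task(tk, constrain_params(tk, th),
                    seed = child_seed(seed, paste0(tk, id, "w", wk)),
                    participant_id = id, week = wk)
    })
    bind_rows(rows)
  })
  names(trials) <- config$tasks
  survey <- generate_survey_items(truth, seed = seed)
  # drop survey weeks where every task session is missing, mirroring
  # participants skipping the whole week
  list(trials = trials, survey = survey, truth = truth)
}
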