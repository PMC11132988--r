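#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement
#' intraclass correlation, from the two-way ANOVA mean squares of a
#' complete participants x sessions matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param mat Numeric matrix, participants in rows (n >= 2), sessions in
#'   columns (k >= 2), no missing cells.
#' @return The ICC(2,1) value.
#' @export
icc_2_1 <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("ICC requires a complete matrix; filter participants first")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) abort("need at least 2 participants and 2 sessions")
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Bootstrapped ICC(2,1) over participants
#'
#' Non-parametric bootstrap of [icc_2_1()]: participants are resampled
#' with replacement `n_boot` times. Two missing-data policies are
#' available: `"complete_case"` keeps only participants with no missing
#' sessions; `"nmax"` keeps all participants but truncates each to their
#' first `nmax` observed sessions (so the matrix is complete by
#' construction).
#'
#' @param mat Participants x sessions matrix, possibly with `NA` cells.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param variant `"complete_case"` or `"nmax"`.
#' @param nmax Number of sessions per participant for the `"nmax"`
#'   variant.
#' @return An `icc_result` list: `icc_point`, `boot` (vector), `median`,
#'   `iqr`, `n_participants`, `n_sessions`, `variant`.
#' @export
bootstrap_icc <- function(mat, n_boot = 1000, seed = 1,
                          variant = c("complete_case", "nmax"), nmax = NULL) {
  variant <- match.arg(variant)
  mat <- as.matrix(mat)
  if (variant == "complete_case") {
    keep <- complete.cases(mat)
    m <- mat[keep, , drop = FALSE]
  } else {
    if (is.null(nmax)) abort("nmax variant requires `nmax`")
    rows <- apply(mat, 1, function(r) {
      obs <- r[!is.na(r)]
      if (length(obs) >= nmax) obs[seq_len(nmax)] else rep(NA_real_, nmax)
    })
    m <- t(rows)
    m <- m[complete.cases(m), , drop = FALSE]
  }
  if (nrow(m) < 2) abort("fewer than 2 usable participants")
  point <- icc_2_1(m)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    # a resample of one participant repeated carries no between-participant
    # information; redraw (rare unless n is tiny)
    repeat {
      idx <- sample.int(nrow(m), replace = TRUE)
      if (length(unique(idx)) >= 2) break
    }
    icc_2_1(m[idx, , drop = FALSE])
  }, numeric(1))
  structure(list(icc_point = point, boot = boot,
                 median = median(boot), iqr = unname(diff(quantile(boot, c(0.25, 0.75)))),
                 n_participants = nrow(m), n_sessions = ncol(m),
                 variant = variant),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC(2,1) =", round(x$icc_point, 3),
      "| bootstrap median", round(x$median, 3),
      "IQR", round(x$iqr, 3),
      "| n =", x$n_participants, "k =", x$n_sessions,
      "(", x$variant, ")\n")
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble(icc = x$icc_point, boot_median = x$median, boot_iqr = x$iqr,
         n_participants = x$n_participants, n_sessions = x$n_sessions,
         variant = x$variant)
}

#' Phenotype matrix in wide (participants x sessions) form
#'
#' Helper turning the long phenotype tibble of one parameter into the
#' matrix consumed by the ICC functions.
#'
#' @param phenotypes Long tibble (`participant_id`, `week`, `parameter`,
#'   `estimate`).
#' @param parameter Which parameter to extract.
#' @param weeks Session columns (default the weeks present).
#' @return Numeric matrix with participants as rows.
#' @export
phenotype_wide <- function(phenotypes, parameter, weeks = NULL) {
  ph <- filter(phenotypes, .data$parameter == !!parameter)
  if (is.null(weeks)) weeks <- sort(unique(ph$week))
  wide <- ph |>
    select("participant_id", "week", "estimate") |>
    tidyr::pivot_wider(names_from = "week", values_from = "estimate")
  m <- as.matrix(wide[as.character(weeks)])
  rownames(m) <- wide$participant_id
  m
}

#' ICC ceiling experiment with a time-constant phenotype
#'
#' Simulates agents whose phenotype is perfectly stable across sessions
#' (drawn once per agent from the task's reference group distribution),
#' fits both the independent and the reduced model, and bootstraps the
#' ICC of each parameter under each fit. Because the generating phenotype
#' does not change, the resulting ICCs estimate the stability ceiling of
#' the design + estimation pipeline; the reduced model, which ignores the
#' participant level, is expected to sit below the independent model.
#'
#' @param task Task code.
#' @param n_agents Number of simulated agents.
#' @param weeks Number of simulated weekly sessions (default 12).
#' @param seed Integer seed.
#' @param chains,iter_warmup,iter_sampling Chain settings for the fits.
#' @param n_boot Bootstrap resamples per ICC.
#' @param group Reference group spec (defaults to
#'   [default_group_spec()] rows for the task).
#' @return Tibble: `parameter`, `model` (independent/reduced),
#'   `icc_median`, `icc_iqr`, `icc_point`.
#' @export
icc_ceiling_experiment <- function(task, n_agents = 20, weeks = 12, seed = 1,
                                   chains = 2, iter_warmup = 500,
                                   iter_sampling = 500, n_boot = 1000,
                                   group = NULL) {
  check_task(task)
  if (is.null(group)) group <- filter(default_group_spec(), .data$task == !!task)
  info <- task_params(task)
  set.seed(child_seed(seed, paste0("ceiling", task)))
  mu <- group$mu_g[match(info$parameter, group$parameter)]
  eta <- group$eta_g[match(info$parameter, group$parameter)]
  rows <- vector("list", n_agents * weeks)
  for (ag in seq_len(n_agents)) {
    th <- rnorm(length(mu), mu, eta)  # constant across all sessions
    pars <- constrain_params(task, setNames(th, info$parameter))
    for (wk in seq_len(weeks)) {
      rows[[(ag - 1) * weeks + wk]] <- simulate_task(
        task, pars, seed = child_seed(seed, paste0(task, ag, "w", wk)),
        participant_id = sprintf("agent%03d", ag), week = wk)
    }
  }
  trials <- bind_rows(rows)
  out <- list()
  for (v in c("independent", "reduced")) {
    fit <- fit_model(trials, task, variant = v, chains = chains,
                     iter_warmup = iter_warmup,
                     iter_sampling = iter_sampling,
                     seed = child_seed(seed, paste0("fit", v)))
    ph <- to_phenotype_matrix(fit, space = "unconstrained", override = TRUE)
    out[[v]] <- bind_rows(lapply(info$parameter, function(pp) {
      ic <- bootstrap_icc(phenotype_wide(ph, pp), n_boot = n_boot,
                          seed = child_seed(seed, paste0("boot", v, pp)))
      tibble(parameter = pp, model = v, icc_median = ic$median,
             icc_iqr = ic$iqr, icc_point = ic$icc_point)
    }))
  }
  bind_rows(out[c("independent", "reduced")])
}

#' Relative contribution of the dynamic sources
#'
#' For a dynamic-model fit, takes the posterior-mean time series of each
#' dynamical term (practice, valence, arousal, noise) per participant in
#' the unconstrained space, measures each term's amplitude as its standard
#' deviation across the participant's observed sessions, and reports the
#' relative contribution `RC_k = sd_k / sum_i sd_i`. Participants with a
#' single observed week are excluded with a warning.
#'
#' @param fit A dynamic-variant `phenodyn_fit`.
#' @return Tibble: `participant_id`, `parameter`, `term`, `sd`, `rc`.
#'   Group summaries are one `dplyr::summarise()` away; RC sums to 1
#'   within participant x parameter.
#' @export
relative_contributions <- function(fit) {
  if (is.null(fit$terms)) abort("relative contributions require a dynamic-model fit")
  counts <- fit$terms |>
    distinct(.data$participant_id, .data$week) |>
    count(.data$participant_id)
  solo <- counts$participant_id[counts$n < 2]
  if (length(solo) > 0) {
    warn(paste0("excluding participants with a single observed week: ",
                paste(solo, collapse = ", ")))
  }
  fit$terms |>
    filter(!.data$participant_id %in% solo) |>
    group_by(.data$participant_id, .data$parameter, .data$term) |>
    summarise(sd = sd(.data$value), .groups = "drop_last") |>
    mutate(rc = .data$sd / sum(.data$sd)) |>
    ungroup()
}

#' Probability of direction
#'
#' The percentage of a posterior sample sharing the sign of its median
#' (range 50..100), with the graded existence label: below 95 "uncertain",
#' then "possibly existing" (>= 95), "likely existing" (>= 97), "probably
#' existing" (>= 99) and "certainly existing" (>= 99.9).
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @return Tibble: `pd` (percentage), `median_sign`, `label`.
#' @export
probability_of_direction <- function(draws) {
  if (length(draws) < 100) abort("need at least 100 draws")
  pd <- 100 * max(mean(draws >= 0), mean(draws <= 0))
  tibble(pd = pd, median_sign = sign(median(draws)), label = pd_label(pd))
}

#' @rdname probability_of_direction
#' @param pd PD percentage value(s).
#' @export
pd_label <- function(pd) {
  cut(pd, breaks = c(-Inf, 95, 97, 99, 99.9, Inf), right = FALSE,
      labels = c("uncertain", "possibly existing", "likely existing",
                 "probably existing", "certainly existing")) |>
    as.character()
}

#' Saturating power-law practice-curve fit with a permutation test
#'
#' Least-squares fit of `y(t) = A - B * t^(-C)` (C > 0) to a weekly
#' series, by profiling: for fixed `C` the model is linear in `(A, B)`, so
#' `C` is optimized on its own. Reports adjusted R-squared with 3 fitted
#' parameters and a session-order permutation p-value: the fraction of
#' `n_perm` random session orders whose refit adjusted R-squared is at
#' least the observed one, with add-one smoothing
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param y Mean per-week series (length >= 4).
#' @param t Time points (default `1..length(y)`, calendar weeks).
#' @param n_perm Number of session-order permutations (default 10000).
#' @param seed Integer seed.
#' @return Tibble: `A`, `B`, `C`, `r2_adj`, `p_perm`, `degenerate`.
#' @export
fit_practice_curve <- function(y, t = seq_along(y), n_perm = 10000, seed = 1) {
  if (length(y) < 4) abort("need at least 4 observed weeks")
  obs <- powerlaw_fit(y, t)
  set.seed(seed)
  n_ge <- 0L
  for (i in seq_len(n_perm)) {
    r2p <- powerlaw_fit(sample(y), t)$r2_adj
    if (r2p >= obs$r2_adj) n_ge <- n_ge + 1L
  }
  tibble(A = obs$A, B = obs$B, C = obs$C, r2_adj = obs$r2_adj,
         p_perm = (1 + n_ge) / (1 + n_perm),
         degenerate = obs$degenerate)
}

powerlaw_fit <- function(y, t) {
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-14) {
    return(list(A = mean(y), B = 0, C = 1, r2_adj = 1 - (n - 1) / (n - 3),
                degenerate = TRUE))
  }
  sse_c <- function(logC) {
    x <- t^(-exp(logC))
    f <- stats::lm.fit(cbind(1, x), y)
    sum(f$residuals^2)
  }
  op <- optimize(sse_c, c(log(1e-3), log(20)))
  C <- exp(op$minimum)
  x <- t^(-C)
  f <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(f$residuals^2) / sst
  list(A = unname(f$coefficients[1]), B = unname(-f$coefficients[2]), C = C,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 3), degenerate = FALSE)
}
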