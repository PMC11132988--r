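#' Evaluate a task model likelihood
#'
#' Dispatches to the task-specific likelihood ([gng_loglik()],
#' [cd_loglik()], [rdm_loglik()], [lt_loglik()], [itc_loglik()],
#' [tab_loglik()], [nc_loglik()]).
#'
#' @param task One of [task_codes()].
#' @param params Constrained-space named parameter list for the task.
#' @param trials Trial tibble for the task.
#' @return The task likelihood list (elements `loglik`, per-trial
#'   probabilities/densities, `n_used`, `n_excluded`).
#' @export
task_loglik <- function(task, params, trials) {
  check_task(task)
  fn <- switch(task, gng = gng_loglik, cd = cd_loglik, rdm = rdm_loglik,
               lt = lt_loglik, itc = itc_loglik, tab = tab_loglik,
               nc = nc_loglik)
  fn(params, trials)
}

#' Simulate one session of a task
#'
#' Dispatches to the matched task simulator; trials are drawn from exactly
#' the generative process the corresponding likelihood scores, under the
#' task's printed design.
#'
#' @inheritParams task_loglik
#' @param design Design list (see [task_design()]).
#' @param seed Integer seed; equal seeds give identical tables.
#' @param participant_id,week Metadata for the generated rows.
#' @return Trial tibble (one weekly session).
#' @export
simulate_task <- function(task, params, design = task_design(task), seed = 1,
                          participant_id = "sim", week = 1L) {
  check_task(task)
  fn <- switch(task, gng = simulate_gng, cd = simulate_cd, rdm = simulate_rdm,
               lt = simulate_lt, itc = simulate_itc, tab = simulate_tab,
               nc = simulate_nc)
  fn(params, design = design, seed = seed, participant_id = participant_id,
     week = week)
}

# log-likelihood as a function of the unconstrained parameter vector theta
task_loglik_unconstrained <- function(task, theta, trials) {
  info <- task_params(task)
  names(theta) <- info$parameter
  task_loglik(task, constrain_params(task, theta), trials)$loglik
}

# Per-session MAP estimate (with a weak Normal(0, reg_sd) regularizer in the
# unconstrained space) and a Laplace standard error per parameter.
# Returns list(est = named vector, se = named vector, convergence).
task_map_session <- function(task, trials, reg_sd = 2.5, init = NULL) {
  info <- task_params(task)
  P <- nrow(info)
  if (is.null(init)) {
    init <- rep(0, P)
    if (task == "rdm") {
      # start the non-decision time inside its support (below min RT)
      min_rt <- min(trials$rt_ms[!is.na(trials$rt_ms)]) / 1000
      init[2] <- log(min_rt / 2)
    }
  }
  cl <- task_fit_closure(task, trials)
  negobj <- function(th) {
    ll <- tryCatch(cl$fn(th), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -(ll + sum(dnorm(th, 0, reg_sd, log = TRUE)))
  }
  neggr <- if (!is.null(cl$gr)) {
    function(th) -(cl$gr(th) - th / reg_sd^2)
  } else NULL
  opt <- optim(init, negobj, gr = neggr, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-9))
  # marginal Laplace s.e. from the full Hessian: with correlated parameters
  # (e.g. an intercept and a slope) the diagonal of the inverse, not the
  # inverse of the diagonal, carries the per-parameter uncertainty
  H <- numeric_hessian(negobj, opt$par)
  se <- rep(reg_sd, P)
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) -1)
  if (all(is.finite(ev)) && min(ev) > 1e-8) {
    se <- sqrt(diag(solve(H)))
  } else {
    d <- diag(H)
    ok <- is.finite(d) & d > 1e-8
    se[ok] <- 1 / sqrt(d[ok])
  }
  list(est = setNames(opt$par, info$parameter),
       se = setNames(pmin(se, reg_sd), info$parameter),
       convergence = opt$convergence)
}

numeric_hessian <- function(fn, x, h = 1e-3) {
  P <- length(x)
  H <- matrix(NA_real_, P, P)
  f0 <- fn(x)
  e <- function(j) { v <- numeric(P); v[j] <- h; v }
  fp <- vapply(seq_len(P), function(j) fn(x + e(j)), numeric(1))
  fm <- vapply(seq_len(P), function(j) fn(x - e(j)), numeric(1))
  diag(H) <- (fp - 2 * f0 + fm) / h^2
  if (P > 1) {
    for (j in seq_len(P - 1)) {
      for (k in (j + 1):P) {
        fpp <- fn(x + e(j) + e(k)); fmm <- fn(x - e(j) - e(k))
        H[j, k] <- H[k, j] <- (fpp - fp[j] - fp[k] + 2 * f0 - fm[j] - fm[k] +
                                 fmm) / (2 * h^2)
      }
    }
  }
  H
}
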