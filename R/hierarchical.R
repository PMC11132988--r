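# Hierarchical statistical models over week-level phenotypes.
#
# Three variants, each applied independently to every task parameter
# (the phenotype is a vector; the hierarchy is scalar per parameter):
#   independent: y_t^s ~ N(mu^s, sigma); mu^s ~ N(mu^g, eta_g);
#                sigma, eta_g ~ HalfNormal(0,1), mu^g ~ N(0,1)
#   reduced:     y_t^s ~ N(mu^g, sigma) (no participant level)
#   dynamic:     y_t^s ~ N(mu^s + delta_p^s (1 - t^(-b^s))
#                          + delta_v^s v_t^s + delta_a^s a_t^s, sigma)
#                delta_i^s = delta_i mu^s, delta_i = 2 Phi(delta_i^prior)-1,
#                delta_i^prior ~ N(0,1); e^-2 < b^s < e with partial pooling
#                on u^s = log b^s via a scaled-logit raw scale.
#
# The practice time index t is the calendar week (1..12), so the practice
# term is exactly 0 at t = 1.

lhalfnorm <- function(x) ifelse(x > 0, log(2) + dnorm(x, log = TRUE), -Inf)

# b^s parameterization: u = log b in (-2, 1) via scaled logit of raw z
b_of_z <- function(z) exp(-2 + 3 * logistic(z))
db_dz <- function(z) {
  sg <- logistic(z)
  b_of_z(z) * 3 * sg * (1 - sg)
}

delta_of <- function(d_prior) 2 * pnorm(d_prior) - 1

# ---------------------------------------------------------------------------
# Scalar-parameter hierarchy over stage-1 session estimates (two-stage fit):
# the latent y is marginalized, yhat_i ~ N(m_i, sigma^2 + se_i^2).
# Sampling space: log for sigma, eta_g, z_sd (with Jacobian).
# Layout (independent): [mu_s (S), mu_g, log_eta, log_sigma]
# Layout (reduced):     [mu_g, log_sigma]
# Layout (dynamic):     [mu_s (S), log_eta, mu_g, log_sigma,
#                        z_raw (S), d_p, d_v, d_a, z_mu, log_z_sd]
# The practice-exponent scores are non-centred (z_s = z_mu + z_sd * z_raw):
# the data inform them weakly, and the centred form funnels against z_sd.
build_hier_model <- function(variant, s_idx, t_idx, yhat, se,
                             v = NULL, a = NULL) {
  S <- max(s_idx)
  n <- length(yhat)
  se2 <- se^2
  if (variant == "dynamic") {
    stopifnot(!is.null(v), !is.null(a), length(v) == n, length(a) == n)
  }
  dims <- switch(variant,
    independent = S + 3L,
    reduced = 2L,
    dynamic = 2L * S + 8L)
  nm <- switch(variant,
    independent = c(paste0("mu_s[", seq_len(S), "]"), "mu_g", "log_eta", "log_sigma"),
    reduced = c("mu_g", "log_sigma"),
    dynamic = c(paste0("mu_s[", seq_len(S), "]"), "log_eta", "mu_g", "log_sigma",
                paste0("z_raw[", seq_len(S), "]"), "d_p", "d_v", "d_a",
                "z_mu", "log_z_sd"))

  unpack <- function(th) {
    switch(variant,
      independent = list(mu_s = th[seq_len(S)], mu_g = th[S + 1],
                         eta = exp(th[S + 2]), sigma = exp(th[S + 3])),
      reduced = list(mu_g = th[1], sigma = exp(th[2])),
      dynamic = {
        z_raw <- th[S + 3 + seq_len(S)]
        z_mu <- th[2 * S + 7]; z_sd <- exp(th[2 * S + 8])
        list(mu_s = th[seq_len(S)], eta = exp(th[S + 1]),
             mu_g = th[S + 2], sigma = exp(th[S + 3]),
             z_raw = z_raw, z_s = z_mu + z_sd * z_raw,
             d_p = th[2 * S + 4], d_v = th[2 * S + 5], d_a = th[2 * S + 6],
             z_mu = z_mu, z_sd = z_sd)
      })
  }

  mean_fn <- function(u) {
    if (variant == "reduced") return(rep(u$mu_g, n))
    if (variant == "independent") return(u$mu_s[s_idx])
    b <- b_of_z(u$z_s)
    A <- 1 - t_idx^(-b[s_idx])
    dp <- delta_of(u$d_p); dv <- delta_of(u$d_v); da <- delta_of(u$d_a)
    u$mu_s[s_idx] * (1 + dp * A + dv * v + da * a)
  }

  lp <- function(th) {
    u <- unpack(th)
    m <- mean_fn(u)
    V <- u$sigma^2 + se2
    out <- sum(-0.5 * log(2 * pi * V) - (yhat - m)^2 / (2 * V))
    out <- out + dnorm(u$mu_g, log = TRUE) +
      lhalfnorm(u$sigma) + log(u$sigma)
    if (variant != "reduced") {
      out <- out + sum(dnorm(u$mu_s, u$mu_g, u$eta, log = TRUE)) +
        lhalfnorm(u$eta) + log(u$eta)
    }
    if (variant == "dynamic") {
      out <- out + sum(dnorm(u$z_raw, log = TRUE)) +
        dnorm(u$d_p, log = TRUE) + dnorm(u$d_v, log = TRUE) +
        dnorm(u$d_a, log = TRUE) + dnorm(u$z_mu, log = TRUE) +
        lhalfnorm(u$z_sd) + log(u$z_sd)
    }
    out
  }

  grad <- function(th) {
    u <- unpack(th)
    g <- numeric(dims)
    V <- u$sigma^2 + se2
    if (variant == "reduced") {
      r <- (yhat - u$mu_g) / V
      g[1] <- sum(r) - u$mu_g
      g[2] <- sum(((yhat - u$mu_g)^2 / V - 1) * u$sigma^2 / V) - u$sigma^2 + 1
      return(g)
    }
    if (variant == "independent") {
      m <- u$mu_s[s_idx]
      r <- (yhat - m) / V
      g[seq_len(S)] <- tapply_sum(r, s_idx, S) - (u$mu_s - u$mu_g) / u$eta^2
      g[S + 1] <- sum(u$mu_s - u$mu_g) / u$eta^2 - u$mu_g
      g[S + 2] <- sum((u$mu_s - u$mu_g)^2) / u$eta^2 - S - u$eta^2 + 1
      g[S + 3] <- sum(((yhat - m)^2 / V - 1) * u$sigma^2 / V) - u$sigma^2 + 1
      return(g)
    }
    # dynamic
    b <- b_of_z(u$z_s)
    bs <- b[s_idx]
    tb <- t_idx^(-bs)
    A <- 1 - tb
    dp <- delta_of(u$d_p); dv <- delta_of(u$d_v); da <- delta_of(u$d_a)
    cmod <- dp * A + dv * v + da * a
    m <- u$mu_s[s_idx] * (1 + cmod)
    r <- (yhat - m) / V
    mus_i <- u$mu_s[s_idx]
    g[seq_len(S)] <- tapply_sum(r * (1 + cmod), s_idx, S) -
      (u$mu_s - u$mu_g) / u$eta^2
    g[S + 1] <- sum((u$mu_s - u$mu_g)^2) / u$eta^2 - S - u$eta^2 + 1
    g[S + 2] <- sum(u$mu_s - u$mu_g) / u$eta^2 - u$mu_g
    g[S + 3] <- sum(((yhat - m)^2 / V - 1) * u$sigma^2 / V) - u$sigma^2 + 1
    # z: through the practice curve only; non-centred chain rule
    dA_dz <- tb * log(t_idx) * bs * (3 * logistic(u$z_s[s_idx]) *
                                       (1 - logistic(u$z_s[s_idx])))
    dlp_dzs <- tapply_sum(r * mus_i * dp * dA_dz, s_idx, S)
    g[S + 3 + seq_len(S)] <- dlp_dzs * u$z_sd - u$z_raw
    g[2 * S + 4] <- sum(r * mus_i * A) * 2 * dnorm(u$d_p) - u$d_p
    g[2 * S + 5] <- sum(r * mus_i * v) * 2 * dnorm(u$d_v) - u$d_v
    g[2 * S + 6] <- sum(r * mus_i * a) * 2 * dnorm(u$d_a) - u$d_a
    g[2 * S + 7] <- sum(dlp_dzs) - u$z_mu
    g[2 * S + 8] <- sum(dlp_dzs * u$z_sd * u$z_raw) - u$z_sd^2 + 1
    g
  }

  list(lp = lp, grad = grad, dims = dims, names = nm, unpack = unpack,
       mean_fn = mean_fn, variant = variant, S = S, n = n)
}

tapply_sum <- function(x, idx, S) {
  out <- numeric(S)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# ---------------------------------------------------------------------------
# Direct log-joint evaluators (natural space, no Jacobians): the trial
# likelihood term plus the hierarchy and hyper-prior terms. Used for
# testing the model algebra and by the joint fitter.

#' Log joint density of the independent hierarchical model
#'
#' Evaluates, for one task, the sum of the trial log-likelihoods at the
#' constrained session-level phenotypes, the session-level normal terms
#' `y_t^s ~ N(mu^s, sigma)`, the participant-level terms
#' `mu^s ~ N(mu^g, eta_g)`, and the hyper-priors (`mu^g ~ N(0,1)`,
#' `sigma, eta_g ~ HalfNormal(0,1)`). Returns `-Inf` when `sigma` or
#' `eta_g` are outside their support.
#'
#' @param theta Named list: `y` (n_sessions x P matrix of unconstrained
#'   phenotypes), `mu_s` (S x P), `mu_g`, `eta_g`, `sigma` (length-P
#'   vectors). P is the task's parameter count; columns follow
#'   [task_params()] order.
#' @param obs Tibble describing the sessions: `participant` (integer index
#'   1..S), `week` (1..12), matching the rows of `theta$y`.
#' @param task Task code; ignored when `loglik_fn` is given.
#' @param trials_by List of trial tibbles, one per row of `obs`.
#' @param loglik_fn Optional `function(theta_row, trials)` returning a
#'   session log-likelihood; overrides the task likelihood (a zero stub is
#'   useful for testing the hierarchy algebra).
#' @return Scalar log joint density.
#' @export
log_joint_independent <- function(theta, obs, task = NULL, trials_by = NULL,
                                  loglik_fn = NULL) {
  with(theta, {
    if (any(sigma <= 0) || any(eta_g <= 0)) return(-Inf)
    P <- length(mu_g)
    out <- session_loglik_sum(theta$y, obs, task, trials_by, loglik_fn)
    for (p in seq_len(P)) {
      out <- out + sum(dnorm(theta$y[, p], mu_s[obs$participant, p],
                             sigma[p], log = TRUE)) +
        sum(dnorm(mu_s[, p], mu_g[p], eta_g[p], log = TRUE)) +
        dnorm(mu_g[p], log = TRUE) + lhalfnorm(sigma[p]) + lhalfnorm(eta_g[p])
    }
    out
  })
}

#' Log joint density of the reduced hierarchical model
#'
#' As [log_joint_independent()] but with no participant level: all
#' sessions are independent draws around the group mean.
#'
#' @inheritParams log_joint_independent
#' @param theta Named list: `y`, `mu_g`, `sigma`.
#' @export
log_joint_reduced <- function(theta, obs, task = NULL, trials_by = NULL,
                              loglik_fn = NULL) {
  with(theta, {
    if (any(sigma <= 0)) return(-Inf)
    P <- length(mu_g)
    out <- session_loglik_sum(theta$y, obs, task, trials_by, loglik_fn)
    for (p in seq_len(P)) {
      out <- out + sum(dnorm(theta$y[, p], mu_g[p], sigma[p], log = TRUE)) +
        dnorm(mu_g[p], log = TRUE) + lhalfnorm(sigma[p])
    }
    out
  })
}

#' Log joint density of the dynamic hierarchical model
#'
#' Session means gain a power-law practice term and affective state terms:
#' `mu^s + delta_p^s (1 - t^(-b^s)) + delta_v^s v_t^s + delta_a^s a_t^s`,
#' with `delta_i^s = delta_i mu^s`, `delta_i = 2 Phi(delta_i^prior) - 1`,
#' `delta_i^prior ~ N(0,1)`, and the practice exponent `b^s` constrained to
#' `(e^-2, e)` via a scaled-logit raw scale `z^s ~ N(z_mu, z_sd)` with
#' `z_mu ~ N(0,1)`, `z_sd ~ HalfNormal(0,1)`. The time index `t` is the
#' calendar week, so the practice term vanishes at week 1.
#'
#' @inheritParams log_joint_independent
#' @param theta As in [log_joint_independent()] plus `z_s` (S x P raw
#'   practice-exponent scores), `d_p`, `d_v`, `d_a`, `z_mu` (length-P),
#'   `z_sd` (length-P, > 0).
#' @param states Tibble with `participant` (index), `week`, `valence`,
#'   `arousal`, normalized to `[-1, 1]` within participant.
#' @export
log_joint_dynamic <- function(theta, obs, states, task = NULL,
                              trials_by = NULL, loglik_fn = NULL) {
  with(theta, {
    if (any(sigma <= 0) || any(eta_g <= 0) || any(z_sd <= 0)) return(-Inf)
    P <- length(mu_g)
    st <- dplyr::left_join(obs, states, by = c("participant", "week"))
    if (anyNA(st$valence) || anyNA(st$arousal)) {
      abort("missing state scores for observed sessions")
    }
    out <- session_loglik_sum(theta$y, obs, task, trials_by, loglik_fn)
    for (p in seq_len(P)) {
      b <- b_of_z(z_s[, p])
      A <- 1 - obs$week^(-b[obs$participant])
      dp <- delta_of(d_p[p]); dv <- delta_of(d_v[p]); da <- delta_of(d_a[p])
      m <- mu_s[obs$participant, p] *
        (1 + dp * A + dv * st$valence + da * st$arousal)
      out <- out + sum(dnorm(theta$y[, p], m, sigma[p], log = TRUE)) +
        sum(dnorm(mu_s[, p], mu_g[p], eta_g[p], log = TRUE)) +
        sum(dnorm(z_s[, p], z_mu[p], z_sd[p], log = TRUE)) +
        dnorm(mu_g[p], log = TRUE) + lhalfnorm(sigma[p]) +
        lhalfnorm(eta_g[p]) + dnorm(d_p[p], log = TRUE) +
        dnorm(d_v[p], log = TRUE) + dnorm(d_a[p], log = TRUE) +
        dnorm(z_mu[p], log = TRUE) + lhalfnorm(z_sd[p])
    }
    out
  })
}

session_loglik_sum <- function(y, obs, task, trials_by, loglik_fn) {
  if (is.null(loglik_fn) && is.null(task)) return(0)
  out <- 0
  for (i in seq_len(nrow(obs))) {
    out <- out + if (!is.null(loglik_fn)) {
      loglik_fn(y[i, ], trials_by[[i]])
    } else {
      task_loglik_unconstrained(task, y[i, ], trials_by[[i]])
    }
  }
  out
}
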