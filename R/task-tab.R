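#' Two-armed bandit likelihood (Kalman filter + probit exploration policy)
#'
#' The learner tracks each arm's reward with a Kalman filter: prior mean
#' `m0` and variance `s0^2` at each block start; after observing reward `r`
#' on the chosen arm with observation-noise variance `tau_obs^2` (`tau_R^2`
#' for risky arms, a near-zero `tau_S^2` for deterministic safe arms), the
#' gain is `kappa = s^2 / (s^2 + tau_obs^2)`, `m <- m + kappa (r - m)`,
#' `s^2 <- (1 - kappa) s^2`. With `V = m1 - m2`, `RU = s1 - s2` and
#' `TU = sqrt(s1^2 + s2^2)`, the choice rule is
#' `p(arm 1) = Phi(w_V V + w_RU RU + w_sTU sign(V)/TU)` with `sign(0) = 0`.
#'
#' The Kalman recursion depends only on the data and the filter
#' configuration, not on the weights, so regressors are computed once and
#' the likelihood is an ordinary probit.
#'
#' @param params Named list with `w_V`, `w_RU`, `w_sTU`.
#' @param trials Bandit trial table: `condition`, `arm1_label`/`arm2_label`
#'   ("R"/"S"), `response` (1 arm 1, 0 arm 2), `outcome` (observed reward).
#'   Blocks reset the filter.
#' @param kalman Filter configuration (`m0`, `s02`, `tau_R2`, `tau_S2`);
#'   defaults from `task_design("tab")`.
#' @return List with `loglik`, `prob`, `p_choose1`, regressor tibble `X`,
#'   `n_used`, `n_excluded`.
#' @export
tab_loglik <- function(params, trials, kalman = task_design("tab")$kalman) {
  p <- as.list(params)
  X <- tab_regressors(trials, kalman)
  z <- p$w_V * X$V + p$w_RU * X$RU + p$w_sTU * X$sTU
  p1 <- pnorm(z)
  pr <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
  prob <- ifelse(is.na(trials$response), NA_real_,
                 ifelse(trials$response == 1, pr, 1 - pr))
  used <- !is.na(prob)
  list(loglik = sum(log(prob[used])), prob = prob, p_choose1 = p1, X = X,
       n_used = sum(used), n_excluded = sum(!used))
}

#' Kalman-filter regressors for the bandit probit policy
#'
#' @inheritParams tab_loglik
#' @return Tibble with per-trial `V`, `RU`, `sTU` (= sign(V)/TU), `TU`,
#'   posterior means/variances before choice.
#' @export
tab_regressors <- function(trials, kalman = task_design("tab")$kalman) {
  if (!all(c(trials$arm1_label, trials$arm2_label) %in% c("R", "S"))) {
    abort("bandit arms must be labelled 'R' or 'S'")
  }
  ord <- order(trials$participant_id, trials$week, trials$block, trials$trial)
  tr <- trials[ord, ]
  grp <- paste(tr$participant_id, tr$week, tr$block)
  n <- nrow(tr)
  V <- RU <- sTU <- TU <- numeric(n)
  m1v <- m2v <- s1v <- s2v <- numeric(n)
  starts <- c(1L, which(grp[-1] != grp[-length(grp)]) + 1L)
  ends <- c(starts[-1] - 1L, n)
  tau2 <- function(lab) if (lab == "R") kalman$tau_R2 else kalman$tau_S2
  for (g in seq_along(starts)) {
    if (ends[g] < starts[g]) abort("empty bandit block")
    m <- c(kalman$m0, kalman$m0); s2 <- c(kalman$s02, kalman$s02)
    for (i in starts[g]:ends[g]) {
      s <- sqrt(s2)
      V[i] <- m[1] - m[2]; RU[i] <- s[1] - s[2]; TU[i] <- sqrt(sum(s2))
      sTU[i] <- sign(V[i]) / TU[i]
      m1v[i] <- m[1]; m2v[i] <- m[2]; s1v[i] <- s2[1]; s2v[i] <- s2[2]
      a <- tr$response[i]
      if (is.na(a) || is.na(tr$outcome[i])) next
      arm <- if (a == 1) 1L else 2L
      lab <- if (arm == 1L) tr$arm1_label[i] else tr$arm2_label[i]
      k <- s2[arm] / (s2[arm] + tau2(lab))
      m[arm] <- m[arm] + k * (tr$outcome[i] - m[arm])
      s2[arm] <- (1 - k) * s2[arm]
    }
  }
  inv <- order(ord)
  tibble(V = V[inv], RU = RU[inv], sTU = sTU[inv], TU = TU[inv],
         m1 = m1v[inv], m2 = m2v[inv], s1_2 = s1v[inv], s2_2 = s2v[inv])
}

#' Simulate one two-armed bandit session
#'
#' 30 ten-trial blocks cycling over the SS/RR/RS/SR label conditions. Arm
#' means are redrawn each block from `Normal(0, block_mean_sd)`; risky arms
#' pay `Normal(mean, sd)` with the block's risky s.d. cycled over
#' `design$risky_sds`, safe arms pay their mean deterministically. Choices
#' are drawn from the same probit policy [tab_loglik()] scores.
#'
#' @inheritParams simulate_gng
#' @export
simulate_tab <- function(params, design = task_design("tab"), seed = 1,
                         participant_id = "sim", week = 1L) {
  p <- as.list(params)
  set.seed(seed)
  kal <- design$kalman
  rows <- vector("list", design$n_blocks)
  conds <- rep(design$conditions, length.out = design$n_blocks)
  rsds <- rep(design$risky_sds, length.out = design$n_blocks)
  for (blk in seq_len(design$n_blocks)) {
    cond <- conds[blk]
    labs <- strsplit(cond, "")[[1]]
    mu_arm <- rnorm(2, 0, design$block_mean_sd)
    m <- c(kal$m0, kal$m0); s2 <- c(kal$s02, kal$s02)
    nt <- design$trials_per_block
    resp <- integer(nt); rew <- numeric(nt)
    for (i in seq_len(nt)) {
      s <- sqrt(s2)
      V <- m[1] - m[2]; RU <- s[1] - s[2]; TU <- sqrt(sum(s2))
      z <- p$w_V * V + p$w_RU * RU + p$w_sTU * sign(V) / TU
      a <- rbinom(1, 1, pnorm(z))
      arm <- if (a == 1) 1L else 2L
      r <- if (labs[arm] == "R") rnorm(1, mu_arm[arm], rsds[blk]) else mu_arm[arm]
      t2 <- if (labs[arm] == "R") kal$tau_R2 else kal$tau_S2
      kg <- s2[arm] / (s2[arm] + t2)
      m[arm] <- m[arm] + kg * (r - m[arm])
      s2[arm] <- (1 - kg) * s2[arm]
      resp[i] <- a; rew[i] <- r
    }
    rows[[blk]] <- tibble(
      participant_id = participant_id, task = "tab", week = as.integer(week),
      block = blk, trial = seq_len(nt), condition = cond,
      arm1_label = labs[1], arm2_label = labs[2],
      response = resp, outcome = rew, rt_ms = NA_real_)
  }
  bind_rows(rows)
}
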