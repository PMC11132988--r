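#' Lottery ticket likelihood (risk-sensitive utility with softmax)
#'
#' The utility of a two-outcome ticket is `U = sum_j p_j * x_j^rho_risk`;
#' the probability of choosing the risky ticket is
#' `logistic(beta * (U_risky - U_safe))`. Trials with a win probability of
#' 100% (`p_hi >= 1`) must be removed before modelling (see
#' [lt_remove_certain()]); they are excluded here and counted.
#'
#' @param params Named list with `rho_risk`, `beta` (both > 0).
#' @param trials Lottery trial table: `p_hi`, `safe_hi`, `safe_lo`,
#'   `risky_hi`, `risky_lo`, `response` (1 risky, 0 safe).
#' @return List with `loglik`, `prob`, `p_risky`, `n_used`, `n_excluded`.
#' @export
lt_loglik <- function(params, trials) {
  p <- as.list(params)
  pay <- as.matrix(trials[c("safe_hi", "safe_lo", "risky_hi", "risky_lo")])
  if (any(pay < 0, na.rm = TRUE)) abort("negative lottery payoffs")
  certain <- trials$p_hi >= 1
  u_safe <- trials$p_hi * trials$safe_hi^p$rho_risk +
    (1 - trials$p_hi) * trials$safe_lo^p$rho_risk
  u_risky <- trials$p_hi * trials$risky_hi^p$rho_risk +
    (1 - trials$p_hi) * trials$risky_lo^p$rho_risk
  p_risky <- logistic(p$beta * (u_risky - u_safe))
  resp <- trials$response
  pr <- pmin(pmax(p_risky, 1e-12), 1 - 1e-12)
  prob <- ifelse(resp == 1, pr, 1 - pr)
  used <- !is.na(prob) & !certain
  prob[certain] <- NA_real_
  list(loglik = sum(log(prob[used])), prob = prob, p_risky = p_risky,
       n_used = sum(used), n_excluded = sum(!used))
}

#' Remove certain-win lottery trials
#'
#' Drops trials whose win probability is 100% before modelling.
#'
#' @param trials Lottery trial table.
#' @return Filtered tibble; attribute `n_removed` records the count.
#' @export
lt_remove_certain <- function(trials) {
  out <- dplyr::filter(trials, .data$p_hi < 1)
  attr(out, "n_removed") <- nrow(trials) - nrow(out)
  out
}

#' Simulate one lottery ticket session
#'
#' Three 10-trial blocks at expected-value scales of roughly $2, $50 and
#' $200; ticket payoffs follow the printed example shape scaled per block,
#' with the high-outcome probability sweeping 0.1..1.0 (the 100% trial is
#' later removed for modelling).
#'
#' @inheritParams simulate_gng
#' @export
simulate_lt <- function(params, design = task_design("lt"), seed = 1,
                        participant_id = "sim", week = 1L) {
  p <- as.list(params)
  set.seed(seed)
  rows <- vector("list", design$n_blocks)
  for (blk in seq_len(design$n_blocks)) {
    sc <- design$ev_scales[blk]
    tt <- tibble(
      participant_id = participant_id, task = "lt", week = as.integer(week),
      block = blk, trial = seq_along(design$p_hi),
      p_hi = sample(design$p_hi),
      safe_hi = sc * design$safe_hi, safe_lo = sc * design$safe_lo,
      risky_hi = sc * design$risky_hi, risky_lo = sc * design$risky_lo)
    u_s <- tt$p_hi * tt$safe_hi^p$rho_risk + (1 - tt$p_hi) * tt$safe_lo^p$rho_risk
    u_r <- tt$p_hi * tt$risky_hi^p$rho_risk + (1 - tt$p_hi) * tt$risky_lo^p$rho_risk
    tt$response <- rbinom(nrow(tt), 1, logistic(p$beta * (u_r - u_s)))
    tt$rt_ms <- NA_real_
    rows[[blk]] <- tt
  }
  bind_rows(rows)
}

#' Intertemporal choice likelihood (hyperbolic discounting with softmax)
#'
#' The present value of an amount `A` at delay `D` days is
#' `V(A, D) = A / (1 + k * D)`; the probability of choosing the delayed
#' option over an immediate amount `A0` is
#' `logistic(beta * (V(A_D, D) - A0))`.
#'
#' @param params Named list with `k` (discount rate per day) and `beta`.
#' @param trials ITC trial table: `amount_now`, `amount_later`,
#'   `delay_days`, `response` (1 delayed, 0 immediate).
#' @return List with `loglik`, `prob`, `p_delayed`, `n_used`, `n_excluded`.
#' @export
itc_loglik <- function(params, trials) {
  p <- as.list(params)
  if (any(trials$amount_now < 0 | trials$amount_later < 0 | trials$delay_days < 0)) {
    abort("negative amounts or delays")
  }
  v_later <- trials$amount_later / (1 + p$k * trials$delay_days)
  p_del <- logistic(p$beta * (v_later - trials$amount_now))
  pr <- pmin(pmax(p_del, 1e-12), 1 - 1e-12)
  prob <- ifelse(is.na(trials$response), NA_real_,
                 ifelse(trials$response == 1, pr, 1 - pr))
  used <- !is.na(prob)
  list(loglik = sum(log(prob[used])), prob = prob, p_delayed = p_del,
       n_used = sum(used), n_excluded = sum(!used))
}

#' Simulate one intertemporal choice session
#'
#' A fixed 27-item menu: delayed amounts crossed with delays and immediate
#' fractions (configurable via `design`).
#'
#' @inheritParams simulate_gng
#' @export
simulate_itc <- function(params, design = task_design("itc"), seed = 1,
                         participant_id = "sim", week = 1L) {
  p <- as.list(params)
  set.seed(seed)
  menu <- expand.grid(amount_later = design$amounts_later,
                      delay_days = design$delays_days,
                      now_frac = design$now_fracs)
  menu <- menu[sample.int(nrow(menu)), ]
  tt <- tibble(
    participant_id = participant_id, task = "itc", week = as.integer(week),
    block = 1L, trial = seq_len(nrow(menu)),
    amount_now = round(menu$amount_later * menu$now_frac, 2),
    amount_later = menu$amount_later, delay_days = menu$delay_days)
  v_later <- tt$amount_later / (1 + p$k * tt$delay_days)
  tt$response <- rbinom(nrow(tt), 1, logistic(p$beta * (v_later - tt$amount_now)))
  tt$rt_ms <- NA_real_
  tt
}

#' Numerosity comparison likelihood (Weber-fraction model)
#'
#' Each cluster's count `a` is encoded as `Normal(a, a^2 w^2)`; the
#' probability of judging cluster 1 as more numerous is
#' `Phi((a1 - a2) / (w * sqrt(a1^2 + a2^2)))`.
#'
#' @param params Named list with Weber fraction `w` (> 0).
#' @param trials NC trial table: `a1`, `a2` (positive, unequal counts),
#'   `response` (1 cluster 1, 0 cluster 2).
#' @return List with `loglik`, `prob`, `p_choose1`, `n_used`, `n_excluded`.
#' @export
nc_loglik <- function(params, trials) {
  p <- as.list(params)
  if (any(trials$a1 <= 0 | trials$a2 <= 0)) abort("non-positive counts")
  if (any(trials$a1 == trials$a2)) abort("equal counts: a1 must differ from a2")
  p1 <- pnorm((trials$a1 - trials$a2) / (p$w * sqrt(trials$a1^2 + trials$a2^2)))
  pr <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
  prob <- ifelse(is.na(trials$response), NA_real_,
                 ifelse(trials$response == 1, pr, 1 - pr))
  used <- !is.na(prob)
  list(loglik = sum(log(prob[used])), prob = prob, p_choose1 = p1,
       n_used = sum(used), n_excluded = sum(!used))
}

#' Simulate one numerosity comparison session
#'
#' 160 trials of paired counts drawn uniformly from the design's count
#' range, never equal.
#'
#' @inheritParams simulate_gng
#' @export
simulate_nc <- function(params, design = task_design("nc"), seed = 1,
                        participant_id = "sim", week = 1L) {
  p <- as.list(params)
  set.seed(seed)
  lo <- design$count_range[1]; hi <- design$count_range[2]
  a1 <- sample(lo:hi, design$n_trials, replace = TRUE)
  a2 <- sample(lo:hi, design$n_trials, replace = TRUE)
  eq <- a1 == a2
  while (any(eq)) {
    a2[eq] <- sample(lo:hi, sum(eq), replace = TRUE)
    eq <- a1 == a2
  }
  p1 <- pnorm((a1 - a2) / (p$w * sqrt(a1^2 + a2^2)))
  tibble(
    participant_id = participant_id, task = "nc", week = as.integer(week),
    block = 1L, trial = seq_len(design$n_trials), a1 = a1, a2 = a2,
    response = rbinom(design$n_trials, 1, p1), rt_ms = NA_real_)
}
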