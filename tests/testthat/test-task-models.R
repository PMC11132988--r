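test_that("gng: pure lapse gives T*log(0.5) exactly", {
  p <- ref_params("gng"); p$xi <- 1
  tr <- simulate_gng(ref_params("gng"), seed = 1)
  ll <- gng_loglik(p, tr)
  expect_equal(ll$loglik, nrow(tr) * log(0.5))
  expect_true(all(abs(ll$p_go - 0.5) < 1e-12))
})

test_that("gng: first-trial Go probability is logistic of the bias", {
  # Q = V = 0 at block start, xi = 0, b = ln 2 -> p(go) = 2/3
  tr <- gng_block("gw", 1L, "reward")
  p <- list(b = log(2), pi = 0.5, eps = 0.3, rho_rp = 2, rho_neut = 1, xi = 0)
  ll <- gng_loglik(p, tr)
  expect_equal(ll$p_go[1], 2 / 3, tolerance = 1e-12)
})

test_that("gng: one rewarded Go updates Q and V by a single RW step", {
  # rho_rp = 2, eps = 0.5, from 0 -> Q(go,s) = V(s) = 1; second trial of the
  # same stimulus sees the updated action weights
  tr <- gng_block(c("gw", "gw"), c(1L, 1L), c("reward", "reward"))
  p <- list(b = 0, pi = 0, eps = 0.5, rho_rp = 2, rho_neut = 1, xi = 0)
  ll <- gng_loglik(p, tr)
  # after the update W(go) - W(nogo) = Q(go,s) = 1 (pi = 0)
  expect_equal(ll$p_go[2], plogis(1), tolerance = 1e-12)
  # with a Pavlovian bias the updated V enters too: W diff = Q + pi * V = 1.5
  p2 <- p; p2$pi <- 0.5
  ll2 <- gng_loglik(p2, tr)
  expect_equal(ll2$p_go[2], plogis(1.5), tolerance = 1e-12)
})

test_that("gng: neutral outcomes reinforce context-dependently", {
  # win condition: neutral acts as -rho_neut; avoid condition: +rho_neut
  p <- list(b = 0, pi = 0, eps = 0.5, rho_rp = 2, rho_neut = 1, xi = 0)
  tr_win <- gng_block(c("gw", "gw"), c(1L, 1L), c("neutral", "neutral"))
  expect_equal(gng_loglik(p, tr_win)$p_go[2], plogis(-0.5), tolerance = 1e-12)
  tr_avoid <- gng_block(c("gal", "gal"), c(1L, 1L), c("neutral", "neutral"))
  expect_equal(gng_loglik(p, tr_avoid)$p_go[2], plogis(0.5), tolerance = 1e-12)
})

test_that("gng: per-trial probabilities stay inside [xi/2, 1 - xi/2]", {
  p <- ref_params("gng"); p$xi <- 0.2
  tr <- simulate_gng(p, seed = 3)
  ll <- gng_loglik(p, tr)
  expect_true(all(ll$p_go >= 0.1 - 1e-12 & ll$p_go <= 0.9 + 1e-12))
})

test_that("cd: single-item flag probability matches the closed form", {
  # N-independent parameters, one item with d = theta:
  # P(flag) = 0.5 + Phi(-sqrt(2) theta / sigma)
  p <- list(sigma0 = 10, theta0 = 30, sigma_slope = 1e-9, theta_slope = 1e-9)
  tr <- tibble::tibble(
    participant_id = "p1", task = "cd", week = 1L, block = 1L, trial = 1L,
    set_size = 3, n_changed = 1L,
    d1 = 30, d2 = NA_real_, d3 = NA_real_, d4 = NA_real_,
    d5 = NA_real_, d6 = NA_real_, d7 = NA_real_, d8 = NA_real_,
    response = 1L, rt_ms = NA_real_, correct = 1L)
  # with only one informative item (others NA), p_diff = P(flag_1)
  ll <- cd_loglik(p, tr)
  expect_equal(ll$p_diff[1], 0.5 + pnorm(-sqrt(2) * 30 / 10), tolerance = 1e-6)
})

test_that("cd: no change and a huge threshold make 'different' vanish", {
  p <- list(sigma0 = 5, theta0 = 5000, sigma_slope = 1e-9, theta_slope = 1e-9)
  tr <- simulate_cd(ref_params("cd"), seed = 2)
  tr0 <- tr[tr$n_changed == 0, ]
  ll <- cd_loglik(p, tr0)
  expect_true(all(ll$p_diff < 1e-8))
})

test_that("cd: zero slopes give identical p(different) for matched d-vectors", {
  p <- list(sigma0 = 8, theta0 = 40, sigma_slope = 1e-12, theta_slope = 1e-12)
  base <- c(20, 50, 90)
  mk <- function(N) {
    d <- matrix(NA_real_, 1, 8)
    d[1, seq_along(base)] <- base  # same informative items at every set size
    out <- tibble::tibble(participant_id = "p1", task = "cd", week = 1L,
                          block = 1L, trial = 1L, set_size = N, n_changed = 3L,
                          response = 1L, rt_ms = NA_real_, correct = 1L)
    out[paste0("d", 1:8)] <- as.data.frame(d)
    out
  }
  p_by_n <- vapply(c(3, 4, 6, 8), function(N) cd_loglik(p, mk(N))$p_diff,
                   numeric(1))
  expect_true(all(abs(p_by_n - p_by_n[1]) < 1e-9))
  # and the value itself matches the per-item product formula
  p_flag <- 1 - (pnorm((40 - base) / (sqrt(2) * 8)) -
                   pnorm((-40 - base) / (sqrt(2) * 8)))
  expect_equal(p_by_n[1], 1 - prod(1 - p_flag), tolerance = 1e-10)
})

test_that("rdm: implied choice probability and mean RT match closed forms", {
  expect_equal(ddm_p_correct(2, 1), 0.88080, tolerance = 1e-4)
  expect_equal(ddm_mean_dt(2, 1) + 0.3, 1.06159, tolerance = 1e-4)
  # zero drift -> chance
  expect_equal(ddm_p_correct(2, 0), 0.5)
})

test_that("rdm: the series density integrates to the boundary probabilities", {
  tg <- seq(5e-4, 30, by = 5e-4)
  for (v in c(0.3, 1, 2)) {
    p_lo <- sum(exp(wiener_lpdf(tg, 1.5, v, 0.5))) * 5e-4
    expect_equal(p_lo, 1 - ddm_p_correct(1.5, v), tolerance = 1e-4)
  }
})

test_that("rdm: likelihood excludes no-response and sub-tau trials", {
  p <- ref_params("rdm")
  tr <- simulate_rdm(p, seed = 5)
  n_na <- sum(is.na(tr$response))
  ll <- rdm_loglik(p, tr)
  expect_equal(ll$n_excluded, n_na)
  tr$rt_ms[1] <- p$tau * 1000 - 50  # below non-decision time
  ll2 <- rdm_loglik(p, tr)
  expect_equal(ll2$n_excluded, n_na + ifelse(is.na(tr$response[1]), 0, 1))
})

test_that("lt: the printed ticket example evaluates to p(risky) = 0.3036", {
  tr <- tibble::tibble(
    participant_id = "p1", task = "lt", week = 1L, block = 1L, trial = 1L,
    p_hi = 0.2, safe_hi = 2.00, safe_lo = 1.60,
    risky_hi = 3.85, risky_lo = 0.10, response = 1L, rt_ms = NA_real_)
  ll <- lt_loglik(list(rho_risk = 1, beta = 1), tr)
  expect_equal(ll$p_risky[1], plogis(0.85 - 1.68), tolerance = 1e-10)
  expect_equal(ll$p_risky[1], 0.3036, tolerance = 1e-3)
})

test_that("lt: beta = 0 and rho -> 0 both give indifference", {
  tr <- simulate_lt(ref_params("lt"), seed = 4)
  tr <- lt_remove_certain(tr)
  expect_true(all(abs(lt_loglik(list(rho_risk = 1, beta = 0), tr)$p_risky - 0.5) < 1e-12))
  pr <- lt_loglik(list(rho_risk = 1e-9, beta = 1), tr)$p_risky
  expect_true(all(abs(pr - 0.5) < 1e-6))
})

test_that("lt: certain-win trials are removed before modelling", {
  tr <- simulate_lt(ref_params("lt"), seed = 4)
  out <- lt_remove_certain(tr)
  expect_equal(attr(out, "n_removed"), sum(tr$p_hi >= 1))
  expect_true(all(out$p_hi < 1))
})

test_that("itc: hyperbolic value and softmax evaluate as stated", {
  # V(10, 30) with k = 0.1 -> 2.5
  tr <- tibble::tibble(
    participant_id = "p1", task = "itc", week = 1L, block = 1L, trial = 1L,
    amount_now = 0, amount_later = 10, delay_days = 30,
    response = 1L, rt_ms = NA_real_)
  ll <- itc_loglik(list(k = 0.1, beta = 1), tr)
  expect_equal(ll$p_delayed[1], plogis(2.5), tolerance = 1e-10)
  # k = 0: $5 now vs $10 delayed, beta = 1 -> logistic(5)
  tr2 <- tr; tr2$amount_now <- 5
  ll2 <- itc_loglik(list(k = 0, beta = 1), tr2)
  expect_equal(ll2$p_delayed[1], plogis(5), tolerance = 1e-10)
  expect_equal(ll2$p_delayed[1], 0.9933, tolerance = 1e-4)
  # beta = 0 -> indifference
  expect_equal(itc_loglik(list(k = 0.1, beta = 0), tr)$p_delayed[1], 0.5)
})

test_that("tab: a single Kalman step matches the hand computation", {
  # m = 0, s2 = 100, tau_obs2 = 10, r = 10 -> kappa = 10/11, m' = s2' = 100/11
  kal <- list(m0 = 0, s02 = 100, tau_R2 = 10, tau_S2 = 1e-6)
  tr <- tibble::tibble(
    participant_id = "p1", task = "tab", week = 1L, block = 1L, trial = 1:2,
    condition = "RR", arm1_label = "R", arm2_label = "R",
    response = c(1L, 1L), outcome = c(10, 10), rt_ms = NA_real_)
  X <- tab_regressors(tr, kal)
  expect_equal(X$m1[2], 100 / 11, tolerance = 1e-12)
  expect_equal(X$s1_2[2], 100 / 11, tolerance = 1e-12)
  # safe arm collapses after one observation
  tr$arm1_label <- "S"
  Xs <- tab_regressors(tr, kal)
  expect_lt(Xs$s1_2[2], 1e-3)
  expect_equal(Xs$m1[2], 10, tolerance = 1e-3)
})

test_that("tab: zero weights give chance and variance never increases", {
  p0 <- list(w_V = 0, w_RU = 0, w_sTU = 0)
  tr <- simulate_tab(ref_params("tab"), seed = 6)
  ll <- tab_loglik(p0, tr)
  expect_true(all(abs(ll$p_choose1 - 0.5) < 1e-12))
  X <- ll$X
  for (blk in unique(tr$block)) {
    i <- which(tr$block == blk)
    expect_true(all(diff(X$s1_2[i]) <= 1e-12))
    expect_true(all(diff(X$s2_2[i]) <= 1e-12))
  }
})

test_that("nc: plug-in probability matches the normal-CDF oracle", {
  tr <- tibble::tibble(
    participant_id = "p1", task = "nc", week = 1L, block = 1L, trial = 1L,
    a1 = 20, a2 = 10, response = 1L, rt_ms = NA_real_)
  ll <- nc_loglik(list(w = 0.2), tr)
  expect_equal(ll$p_choose1[1], pnorm(10 / (0.2 * sqrt(500))), tolerance = 1e-12)
  expect_equal(ll$p_choose1[1], 0.9873, tolerance = 1e-4)
  # infinite noise -> chance; swapping clusters flips the probability
  expect_equal(nc_loglik(list(w = 1e9), tr)$p_choose1[1], 0.5, tolerance = 1e-6)
  tr2 <- tr; tr2$a1 <- 10; tr2$a2 <- 20
  expect_equal(nc_loglik(list(w = 0.2), tr2)$p_choose1[1],
               1 - ll$p_choose1[1], tolerance = 1e-12)
})

test_that("simulators are deterministic given a seed and follow the designs", {
  for (task in task_codes()) {
    a <- simulate_task(task, ref_params(task), seed = 11)
    b <- simulate_task(task, ref_params(task), seed = 11)
    expect_identical(a, b)
    expect_equal(nrow(a), task_design(task)$n_trials_session)
  }
})

test_that("gng simulated at full lapse responds at chance", {
  p <- ref_params("gng"); p$xi <- 1
  sims <- lapply(1:42, function(s) simulate_gng(p, seed = s))
  go_rate <- mean(dplyr::bind_rows(sims)$response)
  expect_equal(go_rate, 0.5, tolerance = 0.01)  # 10^4 trials, binomial error
})

test_that("generating parameters dominate perturbed ones in likelihood", {
  # on a large simulated sample the per-trial log-likelihood at the truth
  # beats a clearly perturbed parameter set (consistency of the
  # simulate -> loglik pairing)
  for (task in task_codes()) {
    p <- ref_params(task)
    sims <- dplyr::bind_rows(lapply(1:12, function(s) {
      simulate_task(task, p, seed = 100 + s, week = 1L,
                    participant_id = sprintf("p%02d", s))
    }))
    if (task == "lt") sims <- lt_remove_certain(sims)
    p_pert <- lapply(p, function(x) if (is.numeric(x)) x * 1.6 + 0.15 else x)
    ll_true <- task_loglik(task, p, sims)$loglik
    ll_pert <- task_loglik(task, p_pert, sims)$loglik
    expect_gt(ll_true, ll_pert)
  }
})

test_that("rdm simulated accuracy tracks the logistic choice law per coherence", {
  p <- ref_params("rdm")
  sims <- dplyr::bind_rows(lapply(1:12, function(s) {
    simulate_rdm(p, seed = 200 + s, participant_id = sprintf("p%02d", s))
  }))
  acc <- tapply(sims$response, sims$coherence, mean, na.rm = TRUE)
  for (cc in as.numeric(names(acc))) {
    pc <- ddm_p_correct(p$alpha, p$delta * cc)
    n_cc <- sum(sims$coherence == cc & !is.na(sims$response))
    # censoring at the deadline trims slow errors a little; allow
    # binomial error plus a small censoring margin
    tol <- 3 * sqrt(pc * (1 - pc) / n_cc) + 0.02
    expect_lt(abs(acc[[as.character(cc)]] - pc), tol)
  }
})
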