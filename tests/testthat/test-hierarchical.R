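stub0 <- function(y, tt) 0

test_that("independent log joint equals the hand-summed normal densities", {
  theta <- list(y = matrix(0, 1, 1), mu_s = matrix(0, 1, 1),
                mu_g = 0, eta_g = 1, sigma = 1)
  obs <- tibble::tibble(participant = 1L, week = 1L)
  lj <- log_joint_independent(theta, obs, loglik_fn = stub0)
  hand <- 3 * dnorm(0, log = TRUE) +
    2 * (log(2) + dnorm(1, log = TRUE))
  expect_equal(lj, hand, tolerance = 1e-10)
  # out-of-support scale parameters
  theta$sigma <- -1
  expect_identical(log_joint_independent(theta, obs, loglik_fn = stub0), -Inf)
})

test_that("session terms are maximal when y sits at the participant baseline", {
  obs <- tibble::tibble(participant = rep(1L, 4), week = 1:4)
  base <- list(mu_s = matrix(0.7, 1, 1), mu_g = 0.5, eta_g = 0.8, sigma = 0.6)
  at <- function(yv) log_joint_independent(
    c(list(y = matrix(yv, 4, 1)), base), obs, loglik_fn = stub0)
  expect_gt(at(rep(0.7, 4)), at(rep(0.9, 4)))
  expect_gt(at(rep(0.7, 4)), at(c(0.7, 0.7, 0.7, 0.2)))
})

test_that("duplicating all participants doubles only the data-dependent part", {
  set.seed(3)
  y <- matrix(rnorm(6), 6, 1)
  obs1 <- tibble::tibble(participant = rep(1:2, each = 3), week = rep(1:3, 2))
  th1 <- list(y = y, mu_s = matrix(c(0.2, -0.1), 2, 1),
              mu_g = 0.1, eta_g = 0.9, sigma = 0.7)
  lj1 <- log_joint_independent(th1, obs1, loglik_fn = stub0)
  obs2 <- tibble::tibble(participant = rep(1:4, each = 3), week = rep(1:3, 4))
  th2 <- list(y = rbind(y, y), mu_s = matrix(c(0.2, -0.1, 0.2, -0.1), 4, 1),
              mu_g = 0.1, eta_g = 0.9, sigma = 0.7)
  lj2 <- log_joint_independent(th2, obs2, loglik_fn = stub0)
  hyper <- dnorm(0.1, log = TRUE) + (log(2) + dnorm(0.7, log = TRUE)) +
    (log(2) + dnorm(0.9, log = TRUE))
  expect_equal(lj2 - hyper, 2 * (lj1 - hyper), tolerance = 1e-10)
})

test_that("reduced log joint drops the participant level and is exchangeable", {
  obs <- tibble::tibble(participant = c(1L, 2L), week = c(1L, 1L))
  th <- list(y = matrix(c(0, 0.4), 2, 1), mu_g = 0, sigma = 1)
  lj <- log_joint_reduced(th, obs, loglik_fn = stub0)
  hand <- dnorm(0, log = TRUE) + dnorm(0.4, log = TRUE) +
    dnorm(0, log = TRUE) + (log(2) + dnorm(1, log = TRUE))
  expect_equal(lj, hand, tolerance = 1e-10)
  # permuting participant labels changes nothing
  th_p <- list(y = matrix(c(0.4, 0), 2, 1), mu_g = 0, sigma = 1)
  expect_equal(log_joint_reduced(th_p, obs, loglik_fn = stub0), lj)
})

test_that("reduced model is the eta -> 0 limit of the independent model", {
  obs <- tibble::tibble(participant = c(1L, 1L, 2L), week = c(1L, 2L, 1L))
  y <- matrix(c(0.3, -0.2, 0.5), 3, 1)
  mu_g <- 0.1; sigma <- 0.8
  lred <- log_joint_reduced(list(y = y, mu_g = mu_g, sigma = sigma),
                            obs, loglik_fn = stub0)
  eta <- 1e-8
  lind <- log_joint_independent(
    list(y = y, mu_s = matrix(mu_g, 2, 1), mu_g = mu_g,
         eta_g = eta, sigma = sigma), obs, loglik_fn = stub0)
  # remove the participant-level densities (peaked at mu_s = mu_g) and the
  # eta prior; what remains is the reduced model
  lind_stripped <- lind - 2 * dnorm(0, 0, eta, log = TRUE) -
    (log(2) + dnorm(eta, log = TRUE))
  expect_equal(lind_stripped, lred, tolerance = 1e-6)
})

test_that("dynamic model reduces to the independent model at zero effects", {
  obs <- tibble::tibble(participant = rep(1:2, each = 3), week = rep(1:3, 2))
  states <- tibble::tibble(participant = rep(1:2, each = 3), week = rep(1:3, 2),
                           valence = runif(6, -1, 1), arousal = runif(6, -1, 1))
  y <- matrix(rnorm(6), 6, 1)
  base <- list(y = y, mu_s = matrix(c(0.4, -0.6), 2, 1), mu_g = 0,
               eta_g = 0.7, sigma = 0.5)
  lind <- log_joint_independent(base, obs, loglik_fn = stub0)
  z_s <- matrix(c(0.2, -0.1), 2, 1)
  ldyn <- log_joint_dynamic(
    c(base, list(z_s = z_s, d_p = 0, d_v = 0, d_a = 0, z_mu = 0, z_sd = 1)),
    obs, states, loglik_fn = stub0)
  const <- sum(dnorm(z_s, 0, 1, log = TRUE)) + 4 * dnorm(0, log = TRUE) +
    (log(2) + dnorm(1, log = TRUE))
  expect_equal(ldyn, lind + const, tolerance = 1e-10)
})

test_that("the practice term vanishes at week 1 and saturates at large t", {
  obs <- tibble::tibble(participant = 1L, week = 1L)
  states <- tibble::tibble(participant = 1L, week = 1L, valence = 0, arousal = 0)
  mk <- function(week, d_p) {
    o <- obs; o$week <- as.integer(week); s <- states; s$week <- o$week
    log_joint_dynamic(
      list(y = matrix(0.5, 1, 1), mu_s = matrix(0.5, 1, 1), mu_g = 0,
           eta_g = 1, sigma = 0.4, z_s = matrix(5, 1, 1),  # b near e
           d_p = d_p, d_v = 0, d_a = 0, z_mu = 0, z_sd = 1), o, s,
      loglik_fn = stub0)
  }
  # at t = 1 the practice term is 0 regardless of d_p: only the d_p prior
  # differs between d_p values
  expect_equal(mk(1, 2) - mk(1, 0),
               dnorm(2, log = TRUE) - dnorm(0, log = TRUE), tolerance = 1e-10)
  # at large t the mean shifts by delta_p * mu_s: y = mu_s(1 + delta) is
  # then the session-term mode
  delta <- 2 * pnorm(2) - 1
  o <- obs; o$week <- 12L; s <- states; s$week <- 12L
  at_y <- function(yv) log_joint_dynamic(
    list(y = matrix(yv, 1, 1), mu_s = matrix(0.5, 1, 1), mu_g = 0,
         eta_g = 1, sigma = 0.4, z_s = matrix(5, 1, 1),
         d_p = 2, d_v = 0, d_a = 0, z_mu = 0, z_sd = 1), o, s,
    loglik_fn = stub0)
  near_sat <- 0.5 * (1 + delta * (1 - 12^(-exp(1) + 1e-9)))
  expect_gt(at_y(near_sat), at_y(0.5))
})

test_that("gradients of all three sampling-space models match finite differences", {
  fd <- function(fn, th, h = 1e-6) {
    vapply(seq_along(th), function(j) {
      e <- numeric(length(th)); e[j] <- h
      (fn(th + e) - fn(th - e)) / (2 * h)
    }, numeric(1))
  }
  set.seed(11)
  n <- 15; S <- 5
  s_idx <- rep(1:S, each = 3); t_idx <- rep(c(1, 4, 8), S)
  yhat <- rnorm(n); se <- runif(n, 0.05, 0.5)
  v <- runif(n, -1, 1); a <- runif(n, -1, 1)
  for (variant in c("independent", "reduced", "dynamic")) {
    bh <- phenodyn:::build_hier_model(variant, s_idx, t_idx, yhat, se,
                                      v = v, a = a)
    for (r in 1:3) {
      th <- rnorm(bh$dims, 0, 0.7)
      g <- bh$grad(th); gn <- fd(bh$lp, th)
      expect_lt(max(abs(g - gn) / pmax(abs(gn), 1e-4)), 1e-4)
    }
  }
})

test_that("the joint-model gradient (hierarchy + trial term) passes finite differences", {
  set.seed(5)
  tr <- dplyr::bind_rows(
    simulate_nc(ref_params("nc"), seed = 1, participant_id = "a", week = 1L),
    simulate_nc(ref_params("nc"), seed = 2, participant_id = "a", week = 2L),
    simulate_nc(ref_params("nc"), seed = 3, participant_id = "b", week = 1L))
  obs <- tibble::tibble(participant_id = c("a", "a", "b"), week = c(1L, 2L, 1L),
                        participant = c(1L, 1L, 2L))
  trials_by <- list(tr[tr$participant_id == "a" & tr$week == 1, ],
                    tr[tr$participant_id == "a" & tr$week == 2, ],
                    tr[tr$participant_id == "b" & tr$week == 1, ])
  info <- task_params("nc")
  maps <- lapply(trials_by, function(tt) phenodyn:::task_map_session("nc", tt))
  yhat <- do.call(rbind, lapply(maps, `[[`, "est"))
  se <- do.call(rbind, lapply(maps, `[[`, "se"))
  fits <- phenodyn:::fit_joint("nc", "independent", obs, trials_by, NULL,
                               yhat, se, info, chains = 2,
                               iter_warmup = 10, iter_sampling = 10, seed = 1)
  expect_length(fits, 1)
})

test_that("HMC recovers the moments of a known Gaussian target", {
  lp <- function(th) sum(dnorm(th, c(1, -2), c(1, 0.5), log = TRUE))
  gr <- function(th) -(th - c(1, -2)) / c(1, 0.25)
  smp <- phenodyn:::hmc_sample(lp, gr, init = c(0, 0), chains = 2,
                               iter_warmup = 300, iter_sampling = 700, seed = 4)
  flat <- apply(smp$draws, 3, c)
  expect_equal(colMeans(flat), c(1, -2), tolerance = 0.1)
  expect_equal(apply(flat, 2, sd), c(1, 0.5), tolerance = 0.15)
  expect_equal(sum(smp$divergences), 0)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(9)
  good <- cbind(rnorm(500), rnorm(500))
  expect_lt(split_rhat(good)$rhat, 1.05)
  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(split_rhat(bad)$rhat, 1.5)
  expect_error(split_rhat(matrix(rnorm(500), ncol = 1)), "2 chains")
})

test_that("identical chains give R-hat at (or just below) 1", {
  x <- rnorm(400)
  expect_equal(split_rhat(cbind(x, x))$rhat, 1, tolerance = 0.02)
})
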