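test_that("icc_2_1 matches the brute-force ANOVA oracle on random matrices", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:12, 1); k <- sample(3:8, 1)
    m <- matrix(rnorm(n * k), n, k)
    expect_equal(icc_2_1(m), icc_aov_oracle(m), tolerance = 1e-10)
  }
})

test_that("icc_2_1 hits the boundary cases", {
  # distinct constant rows -> perfect agreement
  m <- matrix(rep(c(1, 3, 7, 10), 5), 4, 5)
  expect_equal(icc_2_1(m), 1, tolerance = 1e-12)
  # pure noise -> near zero at n = 200, k = 12
  set.seed(32)
  m0 <- matrix(rnorm(200 * 12), 200, 12)
  expect_lt(abs(icc_2_1(m0)), 0.05)
  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("icc_2_1 is invariant to shifting and scaling the matrix", {
  set.seed(33)
  m <- matrix(rnorm(30), 6, 5) + rep(rnorm(6, 0, 2), 5)
  expect_equal(icc_2_1(m + 11.3), icc_2_1(m), tolerance = 1e-10)
  expect_equal(icc_2_1(m * 4.7), icc_2_1(m), tolerance = 1e-10)
})

test_that("bootstrap_icc is deterministic, bounded, and exact on perfect data", {
  m <- matrix(rep(c(1, 3, 7, 10), 6), 4, 6)
  r <- bootstrap_icc(m, n_boot = 200, seed = 5)
  expect_true(all(abs(r$boot - 1) < 1e-10))
  expect_equal(r$iqr, 0, tolerance = 1e-10)
  set.seed(34)
  m2 <- matrix(rnorm(60), 10, 6) + rep(rnorm(10), 6)
  r1 <- bootstrap_icc(m2, n_boot = 300, seed = 9)
  r2 <- bootstrap_icc(m2, n_boot = 300, seed = 9)
  expect_identical(r1$boot, r2$boot)
  expect_true(all(r1$boot >= -1 & r1$boot <= 1))
})

test_that("bootstrap median tracks the point estimate under known reliability", {
  # 50 x 12 with signal sd 1 and noise sd 1: expected ICC about 0.5
  set.seed(35)
  m <- matrix(rnorm(50 * 12), 50, 12) + rep(rnorm(50), 12)
  r <- bootstrap_icc(m, n_boot = 500, seed = 2)
  expect_lt(abs(r$median - r$icc_point), 0.05)
  expect_lt(abs(r$icc_point - 0.5), 0.15)
})

test_that("the nmax variant truncates to the first sessions of each participant", {
  set.seed(36)
  m <- matrix(rnorm(5 * 8), 5, 8) + rep(rnorm(5, 0, 2), 8)
  m[1, 7:8] <- NA  # participant with only 6 sessions
  r <- bootstrap_icc(m, n_boot = 50, seed = 1, variant = "nmax", nmax = 6)
  expect_equal(r$n_participants, 5)
  expect_equal(r$n_sessions, 6)
  # complete-case would drop the participant instead
  rc <- bootstrap_icc(m, n_boot = 50, seed = 1)
  expect_equal(rc$n_participants, 4)
})

test_that("probability of direction matches its sampling definition", {
  expect_equal(probability_of_direction(rep(0.3, 200))$pd, 100)
  expect_equal(probability_of_direction(rep(0.3, 200))$label,
               "certainly existing")
  set.seed(37)
  sym <- rnorm(1e5)
  pd_sym <- probability_of_direction(sym)
  expect_lt(abs(pd_sym$pd - 50), 1)
  expect_equal(pd_sym$label, "uncertain")
  shifted <- rnorm(1e5, qnorm(0.95), 1)
  expect_lt(abs(probability_of_direction(shifted)$pd - 95), 0.5)
  expect_error(probability_of_direction(rnorm(10)), "100 draws")
})

test_that("PD is invariant to monotone sign-preserving transforms", {
  set.seed(38)
  d <- rnorm(5000, 0.8)
  f <- function(x) sign(x) * abs(x)^3
  expect_equal(probability_of_direction(d)$pd,
               probability_of_direction(f(d))$pd)
})

test_that("PD labels follow the graded thresholds", {
  expect_equal(pd_label(c(80, 95, 96.9, 97, 98.9, 99, 99.89, 99.9, 100)),
               c("uncertain", "possibly existing", "possibly existing",
                 "likely existing", "likely existing", "probably existing",
                 "probably existing", "certainly existing",
                 "certainly existing"))
})

test_that("practice-curve fit is exact on a noiseless power law", {
  t <- 1:12
  y <- 0.9 - 0.3 * t^(-1)
  r <- fit_practice_curve(y, t, n_perm = 2000, seed = 3)
  expect_equal(r$r2_adj, 1, tolerance = 1e-6)
  expect_equal(r$A, 0.9, tolerance = 1e-4)
  expect_equal(r$B, 0.3, tolerance = 1e-4)
  expect_equal(r$C, 1, tolerance = 1e-3)
  expect_lte(r$p_perm, 0.01)
})

test_that("constant series are flagged degenerate with non-positive adj. R2", {
  r <- fit_practice_curve(rep(0.7, 8), n_perm = 50, seed = 1)
  expect_true(r$degenerate)
  expect_lte(r$r2_adj, 0)
})

test_that("relative contributions sum to one and rank the injected sources", {
  grp <- dplyr::filter(default_group_spec(), task == "nc")
  grp$delta_p <- 0.6; grp$delta_v <- 0; grp$delta_a <- 0
  cfg <- cohort_config(n_participants = 8, weeks = 8, tasks = "nc",
                       group = grp)
  ch <- generate_cohort(cfg, seed = 17)
  states <- dplyr::select(ch$truth$states, "participant_id", "week",
                          "valence", "arousal")
  fit <- fit_model(ch$trials$nc, "nc", variant = "dynamic", states = states,
                   chains = 2, iter_warmup = 300, iter_sampling = 300,
                   seed = 6)
  rc <- relative_contributions(fit)
  sums <- rc |>
    dplyr::group_by(participant_id, parameter) |>
    dplyr::summarise(s = sum(rc), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-10))
  expect_true(all(rc$rc >= 0 & rc$rc <= 1))
  med <- rc |>
    dplyr::group_by(term) |>
    dplyr::summarise(m = median(rc), .groups = "drop")
  # injected: a large practice effect, no state effects
  expect_gt(med$m[med$term == "practice"], med$m[med$term == "valence"])
  expect_gt(med$m[med$term == "practice"], med$m[med$term == "arousal"])
})

test_that("RC is invariant to a common rescaling of all term series", {
  set.seed(40)
  terms <- tidyr::crossing(participant_id = c("a", "b"), week = 1:6,
                           term = c("practice", "valence", "arousal", "noise"))
  terms$task <- "nc"; terms$parameter <- "w"
  terms$value <- rnorm(nrow(terms))
  fake_fit <- structure(list(terms = terms), class = "phenodyn_fit")
  r1 <- relative_contributions(fake_fit)
  fake2 <- fake_fit; fake2$terms$value <- fake2$terms$value * 7.3
  r2 <- relative_contributions(fake2)
  expect_equal(r1$rc, r2$rc, tolerance = 1e-12)
})
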