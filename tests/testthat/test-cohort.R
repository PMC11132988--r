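test_that("trajectories decompose exactly into the five generative terms", {
  cfg <- cohort_config(n_participants = 6, weeks = 8, tasks = c("nc", "lt"))
  truth <- generate_trajectories(cfg, seed = 5)
  tj <- truth$trajectories
  recomposed <- tj$mu_s + tj$practice + tj$valence_term + tj$arousal_term +
    tj$noise
  expect_equal(tj$y, recomposed, tolerance = 1e-14)
  # practice term is exactly zero at week 1
  expect_true(all(tj$practice[tj$week == 1] == 0))
})

test_that("zero effects and zero noise give constant trajectories", {
  grp <- dplyr::filter(default_group_spec(), task == "nc")
  grp$delta_p <- 0; grp$delta_v <- 0; grp$delta_a <- 0; grp$sigma <- 0
  cfg <- cohort_config(n_participants = 5, weeks = 6, tasks = "nc",
                       group = grp)
  truth <- generate_trajectories(cfg, seed = 8)
  spread <- truth$trajectories |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(s = max(y) - min(y))
  expect_true(all(spread$s < 1e-12))
})

test_that("the practice term saturates towards delta_p^s at large t", {
  grp <- dplyr::filter(default_group_spec(), task == "nc")
  grp$delta_p <- 0.8; grp$sigma <- 0
  cfg <- cohort_config(n_participants = 4, weeks = 12, tasks = "nc",
                       group = grp, b_z_mu = 3, b_z_sd = 0.1)  # b near e
  truth <- generate_trajectories(cfg, seed = 9)
  late <- truth$trajectories |>
    dplyr::filter(week == 12) |>
    dplyr::left_join(truth$participants, by = c("participant_id", "parameter"),
                     suffix = c("", "_p"))
  expect_lt(max(abs(late$practice - late$delta_p_s)), 0.02)
})

test_that("realized noise has the configured s.d. over many participant-weeks", {
  grp <- dplyr::filter(default_group_spec(), task == "nc")
  cfg <- cohort_config(n_participants = 850, weeks = 12, tasks = "nc",
                       group = grp)
  truth <- generate_trajectories(cfg, seed = 10)
  expect_equal(sd(truth$trajectories$noise), grp$sigma[1], tolerance = 0.02)
})

test_that("cohorts are reproducible and have the printed trial counts", {
  cfg <- cohort_config(n_participants = 1, weeks = 2, tasks = task_codes())
  ch1 <- generate_cohort(cfg, seed = 3)
  ch2 <- generate_cohort(cfg, seed = 3)
  expect_identical(ch1$trials, ch2$trials)
  expect_identical(ch1$survey, ch2$survey)
  counts <- c(gng = 240, cd = 200, rdm = 384, lt = 30, itc = 27,
              tab = 300, nc = 160)
  for (tk in names(counts)) {
    per_week <- ch1$trials[[tk]] |>
      dplyr::count(participant_id, week)
    expect_true(all(per_week$n == counts[[tk]]))
    expect_equal(nrow(per_week), 2)  # 1 participant x 2 weeks
  }
})

test_that("a zero-missingness cohort passes inclusion for every participant", {
  cfg <- cohort_config(n_participants = 5, weeks = 8, tasks = c("nc", "itc"),
                       missingness = 0)
  ch <- generate_cohort(cfg, seed = 4)
  for (tk in names(ch$trials)) {
    rep <- apply_inclusion(ch$trials[[tk]])
    expect_true(all(rep$included))
  }
})

test_that("missingness removes sessions at roughly the configured rate", {
  cfg <- cohort_config(n_participants = 40, weeks = 12, tasks = "nc",
                       missingness = 0.25)
  ch <- generate_cohort(cfg, seed = 6)
  frac <- nrow(dplyr::distinct(ch$trials$nc, participant_id, week)) / (40 * 12)
  expect_lt(abs(frac - 0.75), 0.07)
  expect_lt(abs(mean(!ch$truth$mask$observed) - 0.25), 0.07)
})

test_that("survey generation is seed-stable and ordinal on 1..7", {
  cfg <- cohort_config(n_participants = 4, weeks = 4, tasks = "nc")
  truth <- generate_trajectories(cfg, seed = 2)
  s1 <- generate_survey_items(truth, seed = 12)
  s2 <- generate_survey_items(truth, seed = 12)
  expect_identical(s1, s2)
  expect_true(all(s1$response %in% 1:7))
  expect_true(!34 %in% s1$item_id)
  expect_equal(dplyr::n_distinct(s1$item_id), 35)
  expect_error(generate_survey_items(truth, item_spec = tibble::tibble(
    item_id = 1:3, load_v = 0, load_a = 0, noise_sd = 1)), "degenerate")
})

test_that("more item noise lowers the PC-latent correlation monotonically", {
  cfg <- cohort_config(n_participants = 12, weeks = 6, tasks = "nc")
  truth <- generate_trajectories(cfg, seed = 13)
  cors <- vapply(c(0.2, 1.5, 6), function(ns) {
    sv <- generate_survey_items(truth, default_item_spec(noise_sd = ns),
                                seed = 14)
    spec <- default_item_spec()
    st <- compute_state_components(
      sv, valence_items = attr(spec, "valence_items"),
      arousal_items = attr(spec, "arousal_items"))
    j <- dplyr::inner_join(st, truth$states,
                           by = c("participant_id", "week"))
    abs(cor(j$valence_raw, j$valence_latent))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("constrained trajectory values always lie in the parameter domain", {
  cfg <- cohort_config(n_participants = 10, weeks = 8, tasks = task_codes())
  truth <- generate_trajectories(cfg, seed = 15)
  for (tk in task_codes()) {
    info <- task_params(tk)
    tj <- dplyr::filter(truth$trajectories, task == tk)
    tr <- info$transform[match(tj$parameter, info$parameter)]
    cv <- constrain(tj$y, tr)
    expect_true(all(cv[tr == "log"] > 0))
    expect_true(all(cv[tr == "logit"] > 0 & cv[tr == "logit"] < 1))
    expect_true(all(is.finite(cv)))
  }
})
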