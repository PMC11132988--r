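# Shared fixture builders. All data are generated in code at test time.

ref_params <- function(task) {
  switch(task,
    gng = list(b = 0.2, pi = 0.3, eps = 0.2, rho_rp = 2, rho_neut = 1, xi = 0.1),
    cd = list(sigma0 = 6, theta0 = 45, sigma_slope = 1.5, theta_slope = 0.8),
    rdm = list(alpha = 1.5, tau = 0.3, delta = 6),
    lt = list(rho_risk = 0.85, beta = 0.3),
    itc = list(k = 0.02, beta = 0.5),
    tab = list(w_V = 0.15, w_RU = 0.2, w_sTU = 0.5),
    nc = list(w = 0.22))
}

# independent ICC oracle: two-way ANOVA mean squares via stats::aov
icc_aov_oracle <- function(mat) {
  df <- data.frame(y = c(mat),
                   row = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   col = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  ms <- summary(stats::aov(y ~ row + col, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(mat); k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# one hand-built gng block: 1 participant, 1 week, n trials of one stimulus
gng_block <- function(conditions, responses, outcomes) {
  n <- length(responses)
  tibble::tibble(
    participant_id = "p1", task = "gng", week = 1L, block = 1L,
    trial = seq_len(n), condition = conditions,
    stimulus = match(conditions, c("gw", "gal", "ngw", "ngal")),
    response = responses, rt_ms = NA_real_, outcome = outcomes,
    correct = NA_integer_)
}

# small multi-session trial set for fitting tests
small_cohort_trials <- function(task, n_parts = 4, weeks = 3, seed = 7) {
  grp <- dplyr::filter(default_group_spec(), task == !!task)
  grp$delta_p <- 0; grp$delta_v <- 0; grp$delta_a <- 0
  cfg <- cohort_config(n_participants = n_parts, weeks = weeks,
                       tasks = task, group = grp)
  generate_cohort(cfg, seed = seed)
}
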