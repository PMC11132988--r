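#' Change detection likelihood (maximum absolute difference model)
#'
#' Each of the `N` displayed items is compared independently: the encoded
#' colour difference of item `i` is `D_i = d_i + eta` with
#' `eta ~ Normal(0, 2 sigma(N)^2)`, and the item is flagged as changed when
#' `|D_i| > theta(N)`. Both the encoding noise and the detection threshold
#' grow linearly with set size: `sigma(N) = sigma0 + sigma_slope * N`,
#' `theta(N) = theta0 + theta_slope * N`. The observer responds "different"
#' if any item is flagged, so
#' `p("different") = 1 - prod_i (1 - P(flag_i))` with
#' `P(flag_i) = 1 - [Phi((theta - d_i)/(sqrt(2) sigma)) -
#'                   Phi((-theta - d_i)/(sqrt(2) sigma))]`.
#'
#' Colour differences `d_i` are circular hue distances in degrees, treated
#' as linear magnitudes inside the Gaussian flag rule; the multiple-target
#' block uses the same per-item rule.
#'
#' @param params Named list with `sigma0`, `theta0`, `sigma_slope`,
#'   `theta_slope` (constrained space).
#' @param trials Change-detection trial table: `set_size` in {3,4,6,8},
#'   item difference columns `d1`..`d8` (`NA` beyond the set size, 0 for
#'   unchanged items), `response` (1 "different", 0 "same").
#' @return List with `loglik`, `prob` (probability of the observed
#'   response), `p_diff`, `n_used`, `n_excluded`.
#' @export
cd_loglik <- function(params, trials) {
  p <- as.list(params)
  if (!all(trials$set_size %in% c(3, 4, 6, 8))) abort("set size outside {3,4,6,8}")
  d <- as.matrix(trials[paste0("d", 1:8)])
  if (any(d < 0, na.rm = TRUE)) abort("negative item colour differences")
  p_diff <- cd_p_different(p, trials$set_size, d)
  resp <- trials$response
  pd <- pmin(pmax(p_diff, 1e-12), 1 - 1e-12)
  prob <- ifelse(is.na(resp), NA_real_, ifelse(resp == 1, pd, 1 - pd))
  used <- !is.na(prob)
  list(loglik = sum(log(prob[used])), prob = prob, p_diff = p_diff,
       n_used = sum(used), n_excluded = sum(!used))
}

cd_p_different <- function(p, set_size, d) {
  sig <- p$sigma0 + p$sigma_slope * set_size
  th <- p$theta0 + p$theta_slope * set_size
  if (any(sig <= 0) || any(th <= 0)) abort("sigma(N) and theta(N) must be positive")
  s2 <- sqrt(2) * sig  # s.d. of the encoded difference
  p_flag <- 1 - (pnorm((th - d) / s2) - pnorm((-th - d) / s2))
  p_noflag <- 1 - pmin(p_flag, 1 - 1e-15)
  1 - exp(rowSums(log(p_noflag), na.rm = TRUE))
}

#' Simulate one change-detection session
#'
#' Colours are uniform hues on the circle; changed items jump to an
#' independent uniform hue, giving circular distances in `[0, 180]` degrees.
#' Four single-target blocks (set sizes 3/4/6/8, change on half the trials)
#' and one multiple-target block (set size 8, 0-4 changed items).
#'
#' @inheritParams simulate_gng
#' @export
simulate_cd <- function(params, design = task_design("cd"), seed = 1,
                        participant_id = "sim", week = 1L) {
  p <- as.list(params)
  set.seed(seed)
  rows <- vector("list", design$n_blocks)
  for (blk in seq_len(design$n_blocks)) {
    N <- design$set_sizes[blk]
    nt <- design$trials_per_block
    n_changed <- if (blk == design$multi_block) {
      sample(design$multi_changes, nt, replace = TRUE)
    } else {
      rbinom(nt, 1, design$p_change)
    }
    d <- matrix(NA_real_, nt, 8)
    for (i in seq_len(nt)) {
      di <- numeric(N)
      if (n_changed[i] > 0) {
        idx <- sample.int(N, n_changed[i])
        delta <- abs(runif(n_changed[i], -180, 180))
        di[idx] <- pmin(delta, 360 - delta)
      }
      d[i, seq_len(N)] <- di
    }
    pd <- cd_p_different(p, rep(N, nt), d)
    resp <- rbinom(nt, 1, pd)
    rows[[blk]] <- dplyr::bind_cols(
      tibble(
        participant_id = participant_id, task = "cd", week = as.integer(week),
        block = blk, trial = seq_len(nt), set_size = N, n_changed = n_changed),
      as_tibble(setNames(as.data.frame(d), paste0("d", 1:8))),
      tibble(
        response = resp, rt_ms = NA_real_,
        correct = as.integer((resp == 1) == (n_changed > 0))))
  }
  bind_rows(rows)
}
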