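#' Random dot motion likelihood (drift diffusion model)
#'
#' Joint likelihood of choice and reaction time under an unbiased drift
#' diffusion model with boundary separation `alpha`, non-decision time `tau`
#' (seconds) and drift `v = delta * coherence` on each trial (accuracy
#' coding: the upper boundary is the correct response, start point
#' `z = alpha / 2`, unit diffusion). Densities use the dual-series Wiener
#' first-passage density ([wiener_lpdf()]).
#'
#' Trials without a response inside the deadline, or with `rt <= tau`, are
#' excluded from the likelihood and counted in `n_excluded`.
#'
#' @param params Named list with `alpha`, `tau`, `delta` (constrained).
#' @param trials RDM trial table: `coherence`, `response` (1 correct, 0
#'   error, `NA` no response), `rt_ms`.
#' @return List with `loglik`, per-trial `trial_loglik` (log density of the
#'   observed (choice, RT); `NA` for excluded trials), `n_used`,
#'   `n_excluded`.
#' @export
rdm_loglik <- function(params, trials) {
  p <- as.list(params)
  rt <- trials$rt_ms / 1000
  used <- !is.na(trials$response) & !is.na(rt) & rt > p$tau
  t_dec <- rt - p$tau
  v <- p$delta * trials$coherence
  # upper (correct) boundary via reflection of the lower-boundary density
  drift <- ifelse(trials$response == 1, -v, v)
  ll <- rep(NA_real_, nrow(trials))
  ll[used] <- wiener_lpdf(t_dec[used], p$alpha, drift[used], 0.5)
  list(loglik = sum(ll[used]), trial_loglik = ll,
       n_used = sum(used), n_excluded = sum(!used))
}

#' Simulate one random dot motion session
#'
#' Choice and decision time are drawn from the Wiener first-passage
#' distribution that [rdm_loglik()] scores (`method = "inverse"`, the
#' default, inverse-CDF sampling of the series density) or from a
#' path-level Euler simulation of the diffusion (`method = "euler"`).
#' Responses slower than the deadline are recorded as missing.
#'
#' @inheritParams simulate_gng
#' @param method `"inverse"` or `"euler"`.
#' @export
simulate_rdm <- function(params, design = task_design("rdm"), seed = 1,
                         participant_id = "sim", week = 1L,
                         method = c("inverse", "euler")) {
  p <- as.list(params)
  method <- match.arg(method)
  set.seed(seed)
  rows <- vector("list", design$n_blocks)
  per_coh <- design$trials_per_block / length(design$coherences)
  for (blk in seq_len(design$n_blocks)) {
    coh <- sample(rep(design$coherences, per_coh))
    resp <- integer(design$trials_per_block)
    rt <- numeric(design$trials_per_block)
    for (cc in design$coherences) {
      idx <- which(coh == cc)
      v <- p$delta * cc
      fp <- if (method == "inverse") {
        ddm_sample_inverse(length(idx), p$alpha, v)
      } else {
        ddm_simulate_fpt(length(idx), p$alpha, v)
      }
      resp[idx] <- as.integer(fp$upper)
      rt[idx] <- fp$dt_s + p$tau
    }
    late <- is.na(rt) | rt > design$deadline_s
    rows[[blk]] <- tibble(
      participant_id = participant_id, task = "rdm", week = as.integer(week),
      block = blk, trial = seq_len(design$trials_per_block),
      coherence = coh,
      response = ifelse(late, NA_integer_, resp),
      rt_ms = ifelse(late, NA_real_, rt * 1000))
  }
  bind_rows(rows)
}
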