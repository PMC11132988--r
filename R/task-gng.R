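#' Pavlovian Go/No-go likelihood
#'
#' Rescorla-Wagner learning over four stimuli per block with an instrumental
#' Go bias `b`, a Pavlovian bias `pi` acting through the stimulus value
#' `V(s)`, a shared learning rate `eps`, separate effective outcome sizes for
#' reward/punishment (`rho_rp`) and for context-coded neutral outcomes
#' (`rho_neut`), and a lapse rate `xi`. Neutral outcomes reinforce
#' context-dependently: they act as punishments (-rho_neut) in the win
#' conditions and as rewards (+rho_neut) in the avoid conditions.
#'
#' Action weights are `W(go) = Q(go,s) + b + pi * V(s)` and
#' `W(nogo) = Q(nogo,s)`; the Go probability is
#' `(1 - xi) * logistic(W(go) - W(nogo)) + xi / 2`. Only the taken action's
#' `Q` is updated; `V(s)` is updated on every trial of stimulus `s`.
#' Q and V start at zero at each block.
#'
#' @param params Named list/vector with `b`, `pi`, `eps`, `rho_rp`,
#'   `rho_neut`, `xi` (constrained space).
#' @param trials A Go/No-go trial table (may span several sessions; learning
#'   resets at each participant x week x block). Columns: `condition` in
#'   `gw/gal/ngw/ngal`, `stimulus`, `response` (1 Go, 0 No-go), `outcome`
#'   in `reward/neutral/punishment`.
#' @return List with `loglik`, per-trial `prob` (probability of the observed
#'   response; `NA` for trials without a response), `p_go`, `n_used`,
#'   `n_excluded`.
#' @export
gng_loglik <- function(params, trials) {
  p <- as.list(params)
  stopifnot(all(c("b", "pi", "eps", "rho_rp", "rho_neut", "xi") %in% names(p)))
  bad <- !trials$outcome %in% c("reward", "neutral", "punishment") & !is.na(trials$response)
  if (any(bad)) abort("unknown outcome code in Go/No-go trials")

  ord <- order(trials$participant_id, trials$week, trials$block, trials$trial)
  tr <- trials[ord, ]
  grp <- paste(tr$participant_id, tr$week, tr$block)
  p_go <- rep(NA_real_, nrow(tr))
  win_cond <- tr$condition %in% c("gw", "ngw")
  r_eff <- ifelse(tr$outcome == "reward", p$rho_rp,
           ifelse(tr$outcome == "punishment", -p$rho_rp,
                  ifelse(win_cond, -p$rho_neut, p$rho_neut)))
  starts <- c(1L, which(grp[-1] != grp[-length(grp)]) + 1L)
  ends <- c(starts[-1] - 1L, length(grp))
  for (g in seq_along(starts)) {
    if (ends[g] > starts[g] && any(diff(tr$trial[starts[g]:ends[g]]) != 1)) {
      abort("non-contiguous trial order within a Go/No-go block")
    }
  }
  stim <- tr$stimulus; act <- tr$response
  b <- p$b; pii <- p$pi; eps <- p$eps; xi <- p$xi
  for (g in seq_along(starts)) {
    Qgo <- numeric(8); Qng <- numeric(8); V <- numeric(8)
    for (i in starts[g]:ends[g]) {
      s <- stim[i]
      w <- Qgo[s] + b + pii * V[s] - Qng[s]
      p_go[i] <- (1 - xi) / (1 + exp(-w)) + xi / 2
      a <- act[i]
      if (is.na(a)) next  # missing response: no likelihood, no update
      r <- r_eff[i]
      if (a == 1) Qgo[s] <- Qgo[s] + eps * (r - Qgo[s])
      else        Qng[s] <- Qng[s] + eps * (r - Qng[s])
      V[s] <- V[s] + eps * (r - V[s])
    }
  }
  # restore input order
  inv <- order(ord)
  p_go <- p_go[inv]
  resp <- trials$response
  prob <- ifelse(is.na(resp), NA_real_, ifelse(resp == 1, p_go, 1 - p_go))
  used <- !is.na(prob)
  list(loglik = sum(log(prob[used])), prob = prob, p_go = p_go,
       n_used = sum(used), n_excluded = sum(!used))
}

#' Simulate one Go/No-go session
#'
#' Draws trials from the same generative process [gng_loglik()] scores:
#' stimuli are presented in shuffled order (20 per condition per block) and
#' outcomes follow the 80/20 contingency of the task design.
#'
#' @param params Constrained parameter list (see [gng_loglik()]).
#' @param design Design list from `task_design("gng")`.
#' @param seed Integer seed.
#' @param participant_id,week Metadata for the generated rows.
#' @return A Go/No-go trial tibble.
#' @export
simulate_gng <- function(params, design = task_design("gng"), seed = 1,
                         participant_id = "sim", week = 1L) {
  p <- as.list(params)
  set.seed(seed)
  per_cond <- design$trials_per_block / length(design$conditions)
  rows <- vector("list", design$n_blocks)
  for (blk in seq_len(design$n_blocks)) {
    cond <- sample(rep(design$conditions, per_cond))
    stim <- match(cond, design$conditions)
    Qgo <- numeric(4); Qng <- numeric(4); V <- numeric(4)
    resp <- integer(design$trials_per_block)
    outc <- character(design$trials_per_block)
    corr <- integer(design$trials_per_block)
    for (i in seq_len(design$trials_per_block)) {
      s <- stim[i]
      w <- Qgo[s] + p$b + p$pi * V[s] - Qng[s]
      pg <- (1 - p$xi) * logistic(w) + p$xi / 2
      a <- rbinom(1, 1, pg)
      is_win <- cond[i] %in% c("gw", "ngw")
      correct_a <- as.integer(cond[i] %in% c("gw", "gal"))
      acc <- as.integer(a == correct_a)
      contingent <- runif(1) < design$p_contingent
      o <- if (is_win) {
        if ((acc == 1) == contingent) "reward" else "neutral"
      } else {
        if ((acc == 1) == contingent) "neutral" else "punishment"
      }
      r <- switch(o,
        reward = p$rho_rp, punishment = -p$rho_rp,
        neutral = if (is_win) -p$rho_neut else p$rho_neut)
      if (a == 1) Qgo[s] <- Qgo[s] + p$eps * (r - Qgo[s])
      else        Qng[s] <- Qng[s] + p$eps * (r - Qng[s])
      V[s] <- V[s] + p$eps * (r - V[s])
      resp[i] <- a; outc[i] <- o; corr[i] <- acc
    }
    rows[[blk]] <- tibble(
      participant_id = participant_id, task = "gng", week = as.integer(week),
      block = blk, trial = seq_len(design$trials_per_block),
      condition = cond, stimulus = stim, response = resp,
      rt_ms = NA_real_, outcome = outc, correct = corr)
  }
  bind_rows(rows)
}
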