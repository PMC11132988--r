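# Fast per-session likelihood closures in the unconstrained parameter
# space, with analytic gradients where the recursion permits. Exclusion
# sets are frozen when the closure is built (missing responses; certain-win
# lottery trials; rdm no-response trials), matching the audit rules of the
# likelihoods. The bandit Kalman recursion is parameter-free, so its
# regressors are precomputed once.

task_fit_closure <- function(task, trials) {
  switch(task,
    gng = gng_closure(trials),
    cd = cd_closure(trials),
    rdm = rdm_closure(trials),
    lt = lt_closure(trials),
    itc = itc_closure(trials),
    tab = tab_closure(trials),
    nc = nc_closure(trials))
}

# ---- Go/No-go: forward sensitivities through the Rescorla-Wagner recursion
gng_closure <- function(trials) {
  ord <- order(trials$participant_id, trials$week, trials$block, trials$trial)
  tr <- trials[ord, ]
  grp <- paste(tr$participant_id, tr$week, tr$block)
  starts <- c(1L, which(grp[-1] != grp[-length(grp)]) + 1L)
  ends <- c(starts[-1] - 1L, nrow(tr))
  stim <- tr$stimulus; act <- tr$response
  win_cond <- tr$condition %in% c("gw", "ngw")
  # dr/d(rho_rp), dr/d(rho_neut) per trial (constrained space)
  drp <- ifelse(tr$outcome == "reward", 1, ifelse(tr$outcome == "punishment", -1, 0))
  drn <- ifelse(tr$outcome == "neutral", ifelse(win_cond, -1, 1), 0)

  eval_both <- function(th, want_grad) {
    b <- th[1]; pii <- th[2]
    eps <- logistic(th[3]); rho_rp <- exp(th[4]); rho_neut <- exp(th[5])
    xi <- logistic(th[6])
    r_eff <- rho_rp * drp + rho_neut * drn
    ll <- 0
    g <- numeric(6)
    for (gix in seq_along(starts)) {
      Qgo <- numeric(8); Qng <- numeric(8); V <- numeric(8)
      # sensitivities wrt (eps, rho_rp, rho_neut), constrained space
      dQgo <- matrix(0, 8, 3); dQng <- matrix(0, 8, 3); dV <- matrix(0, 8, 3)
      for (i in starts[gix]:ends[gix]) {
        s <- stim[i]
        w <- Qgo[s] + b + pii * V[s] - Qng[s]
        sw <- 1 / (1 + exp(-w))
        pg <- (1 - xi) * sw + xi / 2
        a <- act[i]
        if (!is.na(a)) {
          pa <- if (a == 1) pg else 1 - pg
          ll <- ll + log(pa)
          if (want_grad) {
            sgn <- if (a == 1) 1 / pa else -1 / pa
            swd <- (1 - xi) * sw * (1 - sw)
            dw <- dQgo[s, ] + pii * dV[s, ] - dQng[s, ]
            g[1] <- g[1] + sgn * swd
            g[2] <- g[2] + sgn * swd * V[s]
            g[3] <- g[3] + sgn * swd * dw[1]
            g[4] <- g[4] + sgn * swd * dw[2]
            g[5] <- g[5] + sgn * swd * dw[3]
            g[6] <- g[6] + sgn * (0.5 - sw)
          }
          r <- r_eff[i]
          dr <- c(0, drp[i], drn[i])
          if (a == 1) {
            if (want_grad) dQgo[s, ] <- (1 - eps) * dQgo[s, ] + eps * dr +
                c(r - Qgo[s], 0, 0)
            Qgo[s] <- Qgo[s] + eps * (r - Qgo[s])
          } else {
            if (want_grad) dQng[s, ] <- (1 - eps) * dQng[s, ] + eps * dr +
                c(r - Qng[s], 0, 0)
            Qng[s] <- Qng[s] + eps * (r - Qng[s])
          }
          if (want_grad) dV[s, ] <- (1 - eps) * dV[s, ] + eps * dr +
              c(r - V[s], 0, 0)
          V[s] <- V[s] + eps * (r - V[s])
        }
      }
    }
    if (!want_grad) return(ll)
    # chain to unconstrained space
    jac <- c(1, 1, eps * (1 - eps), rho_rp, rho_neut, xi * (1 - xi))
    list(ll = ll, grad = g * jac)
  }
  list(fn = function(th) eval_both(th, FALSE),
       gr = function(th) eval_both(th, TRUE)$grad)
}

# ---- change detection: analytic gradient of the per-item flag rule
cd_closure <- function(trials) {
  keep <- !is.na(trials$response)
  tr <- trials[keep, ]
  d <- as.matrix(tr[paste0("d", 1:8)])
  N <- tr$set_size
  y <- tr$response
  eval_both <- function(th, want_grad) {
    sigma0 <- exp(th[1]); theta0 <- exp(th[2])
    ssl <- exp(th[3]); tsl <- exp(th[4])
    sig <- sigma0 + ssl * N
    thr <- theta0 + tsl * N
    s2 <- sqrt(2) * sig
    u1 <- (thr - d) / s2
    u2 <- (-thr - d) / s2
    p_noflag <- pmax(pnorm(u1) - pnorm(u2), 1e-15)
    lognf <- rowSums(log(p_noflag), na.rm = TRUE)
    p_same <- exp(lognf)
    pd <- pmin(pmax(1 - p_same, 1e-12), 1 - 1e-12)
    ll <- sum(ifelse(y == 1, log(pd), log(1 - pd)))
    if (!want_grad) return(ll)
    phi1 <- dnorm(u1); phi2 <- dnorm(u2)
    # derivatives of log p_noflag wrt theta(N) and sigma(N)
    dln_dth <- (phi1 + phi2) / s2 / p_noflag
    dln_dsg <- (-phi1 * u1 + phi2 * u2) / sig / p_noflag
    # d ll / d log p_same ; response 1: ll = log(1 - p_same)
    w <- ifelse(y == 1, -p_same / pd, 1)
    g_th <- rowSums(dln_dth, na.rm = TRUE) * w
    g_sg <- rowSums(dln_dsg, na.rm = TRUE) * w
    g <- c(sum(g_sg) * sigma0, sum(g_th) * theta0,
           sum(g_sg * N) * ssl, sum(g_th * N) * tsl)
    list(ll = ll, grad = g)
  }
  list(fn = function(th) eval_both(th, FALSE),
       gr = function(th) eval_both(th, TRUE)$grad)
}

# ---- random dot motion: precomputed data, numeric gradient (series density)
rdm_closure <- function(trials) {
  keep <- trials[!is.na(trials$response) & !is.na(trials$rt_ms), ]
  min_rt <- min(keep$rt_ms) / 1000
  rt <- keep$rt_ms / 1000
  coh <- keep$coherence
  corr <- keep$response == 1
  fn <- function(th) {
    alpha <- exp(th[1]); tau <- exp(th[2]); delta <- exp(th[3])
    if (tau >= min_rt) return(-Inf)
    v <- delta * coh
    drift <- ifelse(corr, -v, v)
    sum(wiener_lpdf(rt - tau, alpha, drift, 0.5))
  }
  list(fn = fn, gr = NULL)
}

# ---- lottery ticket
lt_closure <- function(trials) {
  tr <- lt_remove_certain(trials)
  tr <- tr[!is.na(tr$response), ]
  p <- tr$p_hi; y <- tr$response
  eval_both <- function(th, want_grad) {
    rho <- exp(th[1]); beta <- exp(th[2])
    us <- p * tr$safe_hi^rho + (1 - p) * tr$safe_lo^rho
    ur <- p * tr$risky_hi^rho + (1 - p) * tr$risky_lo^rho
    du <- ur - us
    pr <- pmin(pmax(logistic(beta * du), 1e-12), 1 - 1e-12)
    ll <- sum(ifelse(y == 1, log(pr), log(1 - pr)))
    if (!want_grad) return(ll)
    # d ll / d z with z = beta * du:  y - pr
    resid <- y - pr
    dus <- p * tr$safe_hi^rho * log(tr$safe_hi) +
      (1 - p) * tr$safe_lo^rho * log(tr$safe_lo)
    dur <- p * tr$risky_hi^rho * log(tr$risky_hi) +
      (1 - p) * tr$risky_lo^rho * log(tr$risky_lo)
    g_rho <- sum(resid * beta * (dur - dus)) * rho
    g_beta <- sum(resid * du) * beta
    list(ll = ll, grad = c(g_rho, g_beta))
  }
  list(fn = function(th) eval_both(th, FALSE),
       gr = function(th) eval_both(th, TRUE)$grad)
}

# ---- intertemporal choice
itc_closure <- function(trials) {
  tr <- trials[!is.na(trials$response), ]
  y <- tr$response
  eval_both <- function(th, want_grad) {
    k <- exp(th[1]); beta <- exp(th[2])
    denom <- 1 + k * tr$delay_days
    v <- tr$amount_later / denom
    du <- v - tr$amount_now
    pr <- pmin(pmax(logistic(beta * du), 1e-12), 1 - 1e-12)
    ll <- sum(ifelse(y == 1, log(pr), log(1 - pr)))
    if (!want_grad) return(ll)
    resid <- y - pr
    dv_dk <- -tr$amount_later * tr$delay_days / denom^2
    g_k <- sum(resid * beta * dv_dk) * k
    g_beta <- sum(resid * du) * beta
    list(ll = ll, grad = c(g_k, g_beta))
  }
  list(fn = function(th) eval_both(th, FALSE),
       gr = function(th) eval_both(th, TRUE)$grad)
}

# ---- two-armed bandit: plain probit in precomputed Kalman regressors
tab_closure <- function(trials, kalman = task_design("tab")$kalman) {
  X <- tab_regressors(trials, kalman)
  keep <- !is.na(trials$response)
  y <- trials$response[keep]
  M <- cbind(X$V, X$RU, X$sTU)[keep, , drop = FALSE]
  eval_both <- function(th, want_grad) {
    z <- drop(M %*% th)
    pr <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
    ll <- sum(ifelse(y == 1, log(pr), log(1 - pr)))
    if (!want_grad) return(ll)
    w <- dnorm(z) * ifelse(y == 1, 1 / pr, -1 / (1 - pr))
    list(ll = ll, grad = drop(crossprod(M, w)))
  }
  list(fn = function(th) eval_both(th, FALSE),
       gr = function(th) eval_both(th, TRUE)$grad)
}

# ---- numerosity comparison
nc_closure <- function(trials) {
  tr <- trials[!is.na(trials$response), ]
  y <- tr$response
  q <- (tr$a1 - tr$a2) / sqrt(tr$a1^2 + tr$a2^2)
  eval_both <- function(th, want_grad) {
    w <- exp(th[1])
    z <- q / w
    pr <- pmin(pmax(pnorm(z), 1e-12), 1 - 1e-12)
    ll <- sum(ifelse(y == 1, log(pr), log(1 - pr)))
    if (!want_grad) return(ll)
    wt <- dnorm(z) * ifelse(y == 1, 1 / pr, -1 / (1 - pr))
    # dz/d(log w) = -z
    list(ll = ll, grad = sum(wt * (-z)))
  }
  list(fn = function(th) eval_both(th, FALSE),
       gr = function(th) eval_both(th, TRUE)$grad)
}
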