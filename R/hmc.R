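# Adaptive Hamiltonian Monte Carlo over an arbitrary differentiable log
# density. Warmup adapts the step size by dual averaging (target acceptance
# 0.8) and a diagonal mass matrix from the second half of warmup; the
# number of leapfrog steps is jittered uniformly up to `max_leapfrog`.
# Iterations whose Hamiltonian error exceeds `divergence_threshold` are
# rejected and, during the kept phase, counted as divergent.

hmc_sample <- function(lp, grad, init, chains = 4, iter_warmup = 1000,
                       iter_sampling = 1000, seed = 1, max_leapfrog = 24,
                       target_accept = 0.8, divergence_threshold = 500,
                       quantity_names = NULL) {
  D <- length(init)
  draws <- array(NA_real_, dim = c(iter_sampling, chains, D))
  divergences <- integer(chains)
  accept_rate <- numeric(chains)
  step_sizes <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed(child_seed(seed, paste0("chain", ch)))
    q <- init
    lq <- lp(q); gq <- grad(q)
    if (!is.finite(lq)) abort("log density not finite at the initial point")
    inv_mass <- rep(1, D)
    # dual averaging state (Hoffman & Gelman defaults)
    eps <- find_reasonable_eps(lp, grad, q, inv_mass)
    mu <- log(10 * eps)
    log_eps_bar <- 0; h_bar <- 0
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    warm_buf <- matrix(NA_real_, max(1, floor(iter_warmup / 2)), D)
    n_accept <- 0L; n_total <- 0L

    for (it in seq_len(iter_warmup + iter_sampling)) {
      warmup <- it <= iter_warmup
      p0 <- rnorm(D) / sqrt(inv_mass)
      h0 <- -lq + 0.5 * sum(p0^2 * inv_mass)
      L <- sample.int(max_leapfrog, 1)
      qq <- q; pp <- p0; gg <- gq
      diverged <- FALSE
      for (l in seq_len(L)) {
        pp <- pp + 0.5 * eps * gg
        qq <- qq + eps * (pp * inv_mass)
        lqq <- lp(qq)
        if (!is.finite(lqq)) { diverged <- TRUE; break }
        gg <- grad(qq)
        pp <- pp + 0.5 * eps * gg
      }
      if (!diverged) {
        h1 <- -lqq + 0.5 * sum(pp^2 * inv_mass)
        d_h <- h1 - h0
        if (!is.finite(d_h) || d_h > divergence_threshold) diverged <- TRUE
      }
      if (diverged) {
        a_prob <- 0
        if (!warmup) divergences[ch] <- divergences[ch] + 1L
      } else {
        a_prob <- min(1, exp(-d_h))
        if (runif(1) < a_prob) {
          q <- qq; lq <- lqq; gq <- gg
          if (!warmup) n_accept <- n_accept + 1L
        }
      }
      if (!warmup) n_total <- n_total + 1L

      if (warmup) {
        # dual averaging on the acceptance statistic
        m <- it
        h_bar <- (1 - 1 / (m + t0)) * h_bar + (target_accept - a_prob) / (m + t0)
        log_eps <- mu - sqrt(m) / gamma * h_bar
        w <- m^(-kappa)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
        eps <- exp(log_eps)
        if (it > iter_warmup - nrow(warm_buf)) {
          warm_buf[it - (iter_warmup - nrow(warm_buf)), ] <- q
        }
        if (it == iter_warmup) {
          v <- apply(warm_buf, 2, var)
          v[!is.finite(v) | v < 1e-10] <- 1
          inv_mass <- v  # kinetic covariance ~ posterior covariance
          eps <- exp(log_eps_bar)
        }
      } else {
        draws[it - iter_warmup, ch, ] <- q
      }
    }
    accept_rate[ch] <- if (n_total > 0) n_accept / n_total else NA_real_
    step_sizes[ch] <- eps
  }
  if (!is.null(quantity_names)) dimnames(draws)[[3]] <- quantity_names
  list(draws = draws, divergences = divergences, accept_rate = accept_rate,
       step_size = step_sizes)
}

find_reasonable_eps <- function(lp, grad, q, inv_mass, eps = 0.1) {
  D <- length(q)
  p <- rnorm(D) / sqrt(inv_mass)
  h0 <- -lp(q) + 0.5 * sum(p^2 * inv_mass)
  leap <- function(eps) {
    pp <- p + 0.5 * eps * grad(q)
    qq <- q + eps * (pp * inv_mass)
    lqq <- lp(qq)
    if (!is.finite(lqq)) return(Inf)
    pp <- pp + 0.5 * eps * grad(qq)
    -lqq + 0.5 * sum(pp^2 * inv_mass) - h0
  }
  dh <- leap(eps)
  a <- if (is.finite(dh) && exp(-dh) > 0.5) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^a
    dh <- leap(eps)
    ok <- is.finite(dh) && exp(-dh) > 0.5
    if ((a == 1 && !ok) || (a == -1 && ok)) break
  }
  eps
}

#' Split R-hat and effective sample size
#'
#' Split-chain potential scale reduction (each chain halved, variance ratio
#' over the split halves) and a crude effective sample size from pooled
#' autocorrelations (initial positive sequence estimator).
#'
#' @param x Iterations x chains matrix of one quantity's draws.
#' @return List with `rhat` and `ess`.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) < 2) abort("R-hat requires at least 2 chains")
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  B <- nn * var(means)
  W <- mean(vars)
  if (W < 1e-300) return(list(rhat = 1, ess = nn * m))
  var_plus <- (nn - 1) / nn * W + B / nn
  rhat <- sqrt(var_plus / W)
  # initial positive sequence ESS on split chains
  rho_sum <- 0
  max_lag <- min(nn - 1, 200)
  ac <- sapply(seq_len(m), function(j) {
    xj <- sp[, j] - means[j]
    stats::acf(xj, lag.max = max_lag, plot = FALSE,
               demean = FALSE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(ac * rep(vars, each = max_lag + 1)) ) / var_plus
  t <- 1
  while (t + 1 <= max_lag && (rho[t + 1] + rho[min(t + 2, max_lag + 1)]) > 0) {
    rho_sum <- rho_sum + rho[t + 1] + rho[min(t + 2, max_lag + 1)]
    t <- t + 2
  }
  ess <- m * nn / (1 + 2 * rho_sum)
  list(rhat = rhat, ess = max(1, min(ess, m * nn)))
}
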