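#' Wiener first-passage time density
#'
#' Log density of the first passage through the *lower* boundary of a Wiener
#' diffusion with unit diffusion coefficient, boundary separation `alpha`,
#' drift `v` and relative start point `w` (fraction of `alpha`). Uses the
#' dual small-time/large-time series with an accuracy-optimal switching rule
#' and a truncation-error target of 1e-7 per evaluation.
#'
#' Upper-boundary densities follow by the reflection `(v, w) -> (-v, 1 - w)`.
#'
#' @param t Decision times (seconds, > 0), vectorized.
#' @param alpha Boundary separation (> 0), scalar or vectorized.
#' @param v Drift rate, scalar or vectorized.
#' @param w Relative start point in (0, 1); default 0.5 (unbiased).
#' @param eps Absolute truncation error target.
#' @return Log densities, `-Inf` for non-positive `t`.
#' @export
wiener_lpdf <- function(t, alpha, v, w = 0.5, eps = 1e-7) {
  n <- max(length(t), length(alpha), length(v), length(w))
  t <- rep_len(t, n); alpha <- rep_len(alpha, n)
  v <- rep_len(v, n); w <- rep_len(w, n)
  out <- rep(-Inf, n)
  ok <- is.finite(t) & t > 0
  if (!any(ok)) return(out)
  tt <- t[ok] / alpha[ok]^2  # normalized time

  # terms needed by each series (Navarro & Fuss 2009)
  ks <- 2 + sqrt(pmax(0, -2 * tt * log(2 * eps * sqrt(2 * pi * tt))))
  ks <- pmax(ks, sqrt(tt) + 1)
  ks[2 * eps * sqrt(2 * pi * tt) >= 1] <- 2
  kl <- sqrt(pmax(0, -2 * log(pi * tt * eps)) / (pi^2 * tt))
  kl <- pmax(kl, 1 / (pi * sqrt(tt)))
  kl[pi * tt * eps >= 1] <- 1 / (pi * sqrt(tt[pi * tt * eps >= 1]))

  use_small <- ks < kl
  dens <- numeric(sum(ok))
  wr <- w[ok]

  if (any(use_small)) {
    i <- which(use_small)
    K <- ceiling(max(ks[i]))
    kseq <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    s <- rep(0, length(i))
    for (k in kseq) {
      s <- s + (wr[i] + 2 * k) * exp(-(wr[i] + 2 * k)^2 / (2 * tt[i]))
    }
    dens[i] <- s / sqrt(2 * pi * tt[i]^3)
  }
  if (any(!use_small)) {
    i <- which(!use_small)
    K <- ceiling(max(kl[i]))
    s <- rep(0, length(i))
    for (k in seq_len(K)) {
      s <- s + k * exp(-k^2 * pi^2 * tt[i] / 2) * sin(k * pi * wr[i])
    }
    dens[i] <- pi * s
  }

  dens <- pmax(dens, 0)
  out[ok] <- log(dens) - log(alpha[ok]^2) -
    v[ok] * alpha[ok] * wr - v[ok]^2 * t[ok] / 2
  out
}

#' Closed-form choice probability and mean decision time of the unbiased DDM
#'
#' For a symmetric start (`z = alpha/2`) and unit diffusion, the probability
#' of absorption at the drift-favoured (upper/correct) boundary is
#' `1 / (1 + exp(-alpha * v))`, and the mean decision time (over both
#' boundaries) is `(alpha / (2 v)) * tanh(alpha * v / 2)`.
#'
#' @param alpha Boundary separation.
#' @param v Drift rate.
#' @return `ddm_p_correct()`: probability; `ddm_mean_dt()`: seconds.
#' @export
ddm_p_correct <- function(alpha, v) 1 / (1 + exp(-alpha * v))

#' @rdname ddm_p_correct
#' @export
ddm_mean_dt <- function(alpha, v) {
  ifelse(abs(v) < 1e-12, alpha^2 / 4, (alpha / (2 * v)) * tanh(alpha * v / 2))
}

#' Simulate first-passage times of the unbiased Wiener process
#'
#' Path-level Euler-Maruyama simulation, independent of the series density
#' used by the likelihood; serves as a process-level oracle for the DDM.
#'
#' @param n Number of trials.
#' @param alpha Boundary separation.
#' @param v Drift rate.
#' @param dt Euler step (seconds). The first-passage bias of the scheme is
#'   O(sqrt(dt)); the default keeps it well below the 10 ms scale.
#' @param t_max Give-up time (seconds).
#' @return Tibble with `upper` (logical, drift-favoured boundary) and
#'   `dt_s` (decision time, seconds; `NA` if not absorbed by `t_max`).
#' @export
ddm_simulate_fpt <- function(n, alpha, v, dt = 1e-4, t_max = 20) {
  x <- rep(alpha / 2, n)
  t_abs <- rep(NA_real_, n)
  upper <- rep(NA, n)
  active <- seq_len(n)
  sdt <- sqrt(dt)
  step <- 0L
  max_steps <- ceiling(t_max / dt)
  while (length(active) > 0 && step < max_steps) {
    step <- step + 1L
    x[active] <- x[active] + v * dt + sdt * rnorm(length(active))
    hit_up <- x[active] >= alpha
    hit_lo <- x[active] <= 0
    done <- hit_up | hit_lo
    if (any(done)) {
      idx <- active[done]
      t_abs[idx] <- step * dt
      upper[idx] <- hit_up[done]
      active <- active[!done]
    }
  }
  tibble(upper = upper, dt_s = t_abs)
}

# Inverse-CDF sampler for (boundary, decision time) from the Wiener density
# itself; used by the task simulator so simulation and likelihood share one
# generative process. Grid-based on (0, t_max].
ddm_sample_inverse <- function(n, alpha, v, t_max = 8, n_grid = 4000) {
  tg <- seq(t_max / n_grid, t_max, length.out = n_grid)
  f_up <- exp(wiener_lpdf(tg, alpha, -v, 0.5))   # upper boundary via reflection
  f_lo <- exp(wiener_lpdf(tg, alpha, v, 0.5))
  p_up <- ddm_p_correct(alpha, v)
  up <- runif(n) < p_up
  draw_t <- function(f, m) {
    if (m == 0) return(numeric(0))
    cdf <- cumsum(f); cdf <- cdf / cdf[length(cdf)]
    u <- runif(m)
    tg[pmax(1L, findInterval(u, cdf) + 1L)]
  }
  t_out <- numeric(n)
  t_out[up] <- draw_t(f_up, sum(up))
  t_out[!up] <- draw_t(f_lo, sum(!up))
  tibble(upper = up, dt_s = t_out)
}
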