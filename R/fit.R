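#' Fit a hierarchical statistical model to one task's trial data
#'
#' Fits the independent, reduced or dynamic hierarchical model over the
#' session-level computational phenotype of one task, using an adaptive
#' Hamiltonian Monte Carlo sampler (4 chains, 1,000 warmup and 1,000 kept
#' iterations by default; hyper-parameters initialized at zero in the
#' unconstrained space).
#'
#' Two estimation methods are available. `"joint"` samples the session
#' phenotypes jointly with the hierarchy against the trial likelihoods.
#' `"two_stage"` first computes a regularized per-session MAP estimate with
#' a Laplace standard error for each parameter, then samples the hierarchy
#' with the session likelihood replaced by the Gaussian stage-1 summary
#' (the latent session value integrated out analytically). The two-stage
#' path scales to cohort-sized problems and is the default.
#'
#' @param trials Trial tibble for the task (several participants/weeks).
#' @param task One of [task_codes()].
#' @param variant `"independent"`, `"reduced"` or `"dynamic"`.
#' @param states For the dynamic variant: a state tibble with
#'   `participant_id`, `week`, `valence`, `arousal` normalized to
#'   `[-1, 1]` within participant (see [normalize_states()]).
#' @param method `"two_stage"` or `"joint"`.
#' @param chains,iter_warmup,iter_sampling MCMC contract (defaults 4,
#'   1000, 1000; scale down for quick runs).
#' @param seed Integer seed; fits are reproducible given the seed.
#' @param max_leapfrog Upper bound of the jittered leapfrog trajectory;
#'   defaults to 24 (64 for the dynamic variant, whose
#'   practice-asymptote/exponent ridge mixes slowly under short
#'   trajectories).
#' @return A `phenodyn_fit` object: posterior draws of all hierarchy
#'   quantities, session-level phenotype posterior means in both spaces,
#'   dynamic term decompositions (dynamic variant), convergence
#'   diagnostics and metadata.
#' @export
fit_model <- function(trials, task, variant = c("independent", "reduced", "dynamic"),
                      states = NULL, method = c("two_stage", "joint"),
                      chains = 4, iter_warmup = 1000, iter_sampling = 1000,
                      seed = 1, max_leapfrog = NULL) {
  check_task(task)
  variant <- match.arg(variant)
  method <- match.arg(method)
  # the dynamic posterior has a practice-asymptote/exponent ridge that
  # needs longer trajectories to traverse
  if (is.null(max_leapfrog)) max_leapfrog <- if (variant == "dynamic") 64 else 24
  if (variant == "dynamic" && is.null(states)) {
    abort("the dynamic model requires `states`")
  }
  info <- task_params(task)
  P <- nrow(info)

  if (task == "lt") trials <- lt_remove_certain(trials)
  obs_keys <- trials |>
    distinct(.data$participant_id, .data$week) |>
    arrange(.data$participant_id, .data$week)
  parts <- sort(unique(obs_keys$participant_id), method = "radix")
  obs <- obs_keys |>
    mutate(participant = match(.data$participant_id, parts))
  S <- length(parts)
  n_obs <- nrow(obs)
  trials_by <- lapply(seq_len(n_obs), function(i) {
    trials[trials$participant_id == obs$participant_id[i] &
             trials$week == obs$week[i], ]
  })

  st <- NULL
  if (variant == "dynamic") {
    st <- obs |>
      left_join(states, by = c("participant_id", "week"))
    if (anyNA(st$valence) || anyNA(st$arousal)) {
      abort("states missing for some observed sessions")
    }
  }

  # ---- stage 1: per-session MAP + Laplace SE (also used to init joint fits)
  maps <- lapply(trials_by, function(tt) task_map_session(task, tt))
  yhat <- do.call(rbind, lapply(maps, `[[`, "est"))
  se <- do.call(rbind, lapply(maps, `[[`, "se"))
  colnames(yhat) <- colnames(se) <- info$parameter

  if (method == "two_stage") {
    fits <- lapply(seq_len(P), function(p) {
      bh <- build_hier_model(variant, obs$participant, obs$week,
                             yhat[, p], se[, p],
                             v = st$valence, a = st$arousal)
      smp <- hmc_sample(bh$lp, bh$grad, init = rep(0, bh$dims),
                        chains = chains, iter_warmup = iter_warmup,
                        iter_sampling = iter_sampling,
                        seed = child_seed(seed, paste0(task, variant, p)),
                        max_leapfrog = max_leapfrog,
                        quantity_names = bh$names)
      list(bh = bh, smp = smp)
    })
  } else {
    fits <- fit_joint(task, variant, obs, trials_by, st, yhat, se, info,
                      chains, iter_warmup, iter_sampling, seed, max_leapfrog)
  }

  out <- assemble_fit(fits, task, variant, method, obs, parts, info,
                      yhat, se, st, seed, chains, iter_warmup, iter_sampling)
  out
}

# Joint fitting: latent session phenotypes sampled against the trial
# likelihoods. Returns the same per-parameter structure as the two-stage
# path, marginal draws extracted from the joint chain.
fit_joint <- function(task, variant, obs, trials_by, st, yhat, se, info,
                      chains, iter_warmup, iter_sampling, seed,
                      max_leapfrog = 24) {
  P <- nrow(info)
  n <- nrow(obs)
  S <- max(obs$participant)
  closures <- lapply(trials_by, function(tt) task_fit_closure(task, tt))
  hdim <- switch(variant, independent = S + 3L, reduced = 2L,
                 dynamic = 2L * S + 8L)
  dims <- n * P + hdim * P
  y_ix <- function(p) (p - 1L) * n + seq_len(n)
  h_ix <- function(p) n * P + (p - 1L) * hdim + seq_len(hdim)

  hier <- function(p, y) build_hier_model(variant, obs$participant, obs$week,
                                          y, rep(0, n),
                                          v = st$valence, a = st$arousal)
  lp <- function(th) {
    out <- 0
    Y <- matrix(th[seq_len(n * P)], n, P)
    for (p in seq_len(P)) {
      bh <- hier(p, Y[, p])
      out <- out + bh$lp(th[h_ix(p)])
    }
    for (i in seq_len(n)) {
      li <- closures[[i]]$fn(Y[i, ])
      if (!is.finite(li)) return(-Inf)
      out <- out + li
    }
    out
  }
  grad <- function(th) {
    g <- numeric(dims)
    Y <- matrix(th[seq_len(n * P)], n, P)
    for (p in seq_len(P)) {
      bh <- hier(p, Y[, p])
      thp <- th[h_ix(p)]
      g[h_ix(p)] <- bh$grad(thp)
      u <- bh$unpack(thp)
      m <- bh$mean_fn(u)
      g[y_ix(p)] <- -(Y[, p] - m) / u$sigma^2
    }
    for (i in seq_len(n)) {
      gi <- if (!is.null(closures[[i]]$gr)) {
        closures[[i]]$gr(Y[i, ])
      } else {
        numgrad(closures[[i]]$fn, Y[i, ])
      }
      g[seq(i, n * P, by = n)] <- g[seq(i, n * P, by = n)] + gi
    }
    g
  }
  init <- numeric(dims)
  init[seq_len(n * P)] <- as.numeric(yhat)  # latents start at stage-1 MAP
  nm <- c(paste0("y[", rep(seq_len(n), P), ",", rep(info$parameter, each = n), "]"),
          unlist(lapply(seq_len(P), function(p) {
            paste0(hier(p, yhat[, p])$names, "[", info$parameter[p], "]")
          })))
  smp <- hmc_sample(lp, grad, init, chains = chains,
                    iter_warmup = iter_warmup, iter_sampling = iter_sampling,
                    seed = child_seed(seed, paste0(task, variant, "joint")),
                    max_leapfrog = max_leapfrog, quantity_names = nm)
  # split back into per-parameter structures
  lapply(seq_len(P), function(p) {
    bh <- build_hier_model(variant, obs$participant, obs$week,
                           yhat[, p], se[, p],
                           v = st$valence, a = st$arousal)
    sub <- smp$draws[, , h_ix(p), drop = FALSE]
    dimnames(sub)[[3]] <- bh$names
    list(bh = bh, smp = list(draws = sub, divergences = smp$divergences,
                             accept_rate = smp$accept_rate,
                             step_size = smp$step_size),
         y_draws = smp$draws[, , y_ix(p), drop = FALSE])
  })
}

numgrad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

# Build the phenodyn_fit object: phenotype posterior means (both spaces),
# dynamic term decompositions, hyper-quantity draws, diagnostics.
assemble_fit <- function(fits, task, variant, method, obs, parts, info,
                         yhat, se, st, seed, chains, iter_warmup,
                         iter_sampling) {
  P <- nrow(info)
  n <- nrow(obs)
  set.seed(child_seed(seed, "posterior-y"))

  phen <- vector("list", P)
  terms <- vector("list", P)
  hyper_draws <- vector("list", P)
  diag_rows <- vector("list", P)
  y_keep <- vector("list", P)
  for (p in seq_len(P)) {
    bh <- fits[[p]]$bh
    dr <- fits[[p]]$smp$draws
    K <- dim(dr)[1] * dim(dr)[2]
    flat <- matrix(aperm(dr, c(1, 2, 3)), K, dim(dr)[3])
    colnames(flat) <- dimnames(dr)[[3]]

    if (!is.null(fits[[p]]$y_draws)) {
      ydr <- fits[[p]]$y_draws
      Ymat <- t(matrix(aperm(ydr, c(1, 2, 3)), K, n))  # n x K
      Emat <- Ymat
    } else {
      # conditional posterior of the latent session value given the draws
      ms <- vapply(seq_len(K), function(k) {
        u <- bh$unpack(flat[k, ])
        bh$mean_fn(u)
      }, numeric(n))                      # n x K prior means
      sig2 <- vapply(seq_len(K), function(k) bh$unpack(flat[k, ])$sigma^2,
                     numeric(1))
      se2 <- se[, p]^2
      prec <- outer(1 / se2, 1 / sig2, `+`)
      Emat <- (yhat[, p] / se2 + sweep(ms, 2, sig2, `/`)) / prec
      Ymat <- Emat + matrix(rnorm(n * K), n, K) / sqrt(prec)
    }
    est_u <- rowMeans(Emat)
    est_c <- rowMeans(constrain(Ymat, info$transform[p]))
    thin <- unique(round(seq(1, K, length.out = min(400, K))))
    y_keep[[p]] <- Ymat[, thin, drop = FALSE]
    phen[[p]] <- tibble(
      participant_id = obs$participant_id, week = obs$week,
      task = task, parameter = info$parameter[p],
      estimate = est_c, estimate_unconstrained = est_u)

    if (variant == "dynamic") {
      # per-draw term values at the observed sessions
      tm <- matrix(0, n, 4)
      for (k in seq_len(K)) {
        u <- bh$unpack(flat[k, ])
        b <- b_of_z(u$z_s)
        A <- 1 - obs$week^(-b[obs$participant])
        mus_i <- u$mu_s[obs$participant]
        pr <- delta_of(u$d_p) * mus_i * A
        va <- delta_of(u$d_v) * mus_i * st$valence
        ar <- delta_of(u$d_a) * mus_i * st$arousal
        noise <- Ymat[, k] - (mus_i + pr + va + ar)
        tm <- tm + cbind(pr, va, ar, noise)
      }
      tm <- tm / K
      terms[[p]] <- tibble(
        participant_id = rep(obs$participant_id, 4),
        week = rep(obs$week, 4), task = task,
        parameter = info$parameter[p],
        term = rep(c("practice", "valence", "arousal", "noise"), each = n),
        value = c(tm))
    }

    qn <- dimnames(dr)[[3]]
    keep_q <- !grepl("^(mu_s|z_s|z_raw)\\[", qn)
    hd <- lapply(which(keep_q), function(j) {
      tibble(parameter = info$parameter[p], quantity = qn[j],
             chain = rep(seq_len(dim(dr)[2]), each = dim(dr)[1]),
             iteration = rep(seq_len(dim(dr)[1]), dim(dr)[2]),
             value = c(dr[, , j]))
    })
    hyper_draws[[p]] <- bind_rows(hd)

    diag_rows[[p]] <- bind_rows(lapply(seq_len(dim(dr)[3]), function(j) {
      sr <- split_rhat(dr[, , j])
      tibble(parameter = info$parameter[p], quantity = qn[j],
             rhat = sr$rhat, ess = sr$ess)
    }))
  }

  structure(list(
    task = task, variant = variant, method = method,
    obs = obs, participants = parts, param_info = info,
    stage1 = list(yhat = yhat, se = se),
    y_draws = setNames(y_keep, info$parameter),
    phenotype = bind_rows(phen),
    terms = if (variant == "dynamic") bind_rows(terms) else NULL,
    draws = bind_rows(hyper_draws),
    diagnostics = bind_rows(diag_rows),
    divergences = sum(vapply(fits, function(f) sum(f$smp$divergences), numeric(1))),
    accept_rate = mean(vapply(fits, function(f) mean(f$smp$accept_rate), numeric(1))),
    seed = seed, chains = chains,
    iter_warmup = iter_warmup, iter_sampling = iter_sampling,
    states = st
  ), class = "phenodyn_fit")
}

#' @export
print.phenodyn_fit <- function(x, ...) {
  cat("<phenodyn_fit> task:", x$task, " variant:", x$variant,
      " method:", x$method, "\n")
  cat("  participants:", length(x$participants),
      " sessions:", nrow(x$obs),
      " chains:", x$chains, "x(", x$iter_warmup, "+", x$iter_sampling, ")\n")
  cat("  max split R-hat:", round(max(x$diagnostics$rhat), 4),
      " divergences:", x$divergences, "\n")
  invisible(x)
}

#' Convergence diagnostics of a hierarchical fit
#'
#' Split R-hat and effective sample size per sampled quantity plus the
#' divergence count; the fit passes when `max(rhat) <= rhat_max` and there
#' are no divergences.
#'
#' @param fit A `phenodyn_fit`.
#' @param rhat_max Pass threshold for split R-hat (default 1.01).
#' @return Tibble of per-quantity diagnostics with attributes
#'   `divergences` and `pass`.
#' @export
convergence_diagnostics <- function(fit, rhat_max = 1.01) {
  out <- fit$diagnostics
  attr(out, "divergences") <- fit$divergences
  attr(out, "pass") <- max(out$rhat) <= rhat_max && fit$divergences == 0
  out
}

#' Extract the phenotype matrix from a fit
#'
#' Posterior-mean point estimates of every session-level phenotype value,
#' in constrained space by default (the unconstrained posterior mean is the
#' `estimate_unconstrained` column). Refuses when the fit's convergence
#' diagnostics fail, unless `override = TRUE`.
#'
#' @param fit A `phenodyn_fit`.
#' @param space `"constrained"` or `"unconstrained"`.
#' @param override Extract despite failing diagnostics?
#' @param rhat_max Diagnostic threshold passed to
#'   [convergence_diagnostics()].
#' @return Tibble: `participant_id`, `week`, `task`, `parameter`,
#'   `estimate`.
#' @export
to_phenotype_matrix <- function(fit, space = c("constrained", "unconstrained"),
                                override = FALSE, rhat_max = 1.01) {
  space <- match.arg(space)
  dg <- convergence_diagnostics(fit, rhat_max)
  if (!attr(dg, "pass") && !override) {
    abort(paste0("fit failed convergence diagnostics (max R-hat = ",
                 round(max(dg$rhat), 3), ", divergences = ",
                 attr(dg, "divergences"),
                 "); pass override = TRUE to extract anyway"))
  }
  out <- fit$phenotype
  if (space == "unconstrained") {
    out$estimate <- out$estimate_unconstrained
  }
  select(out, "participant_id", "week", "task", "parameter", "estimate")
}

#' Tidy posterior summaries of a hierarchical fit
#'
#' Broom-style summary of the group-level quantities (posterior mean,
#' standard deviation and central credible interval); for the dynamic
#' variant the population effect fractions `delta_p`, `delta_v`, `delta_a`
#' are reported on their natural (-1, 1) scale.
#'
#' @param x A `phenodyn_fit`.
#' @param conf_level Credible-interval mass (default 0.9).
#' @param ... Unused.
#' @return Tibble: `parameter`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.phenodyn_fit <- function(x, conf_level = 0.9, ...) {
  dr <- x$draws |>
    mutate(
      term = dplyr::recode(.data$quantity,
        "log_eta" = "eta_g", "log_sigma" = "sigma", "log_z_sd" = "z_sd",
        "d_p" = "delta_p", "d_v" = "delta_v", "d_a" = "delta_a"),
      value = dplyr::case_when(
        .data$quantity %in% c("log_eta", "log_sigma", "log_z_sd") ~ exp(.data$value),
        .data$quantity %in% c("d_p", "d_v", "d_a") ~ delta_of(.data$value),
        TRUE ~ .data$value))
  a <- (1 - conf_level) / 2
  dr |>
    group_by(.data$parameter, .data$term) |>
    summarise(estimate = mean(.data$value), std.error = sd(.data$value),
              conf.low = quantile(.data$value, a),
              conf.high = quantile(.data$value, 1 - a), .groups = "drop")
}

#' One-row fit summary
#'
#' @param x A `phenodyn_fit`.
#' @param ... Unused.
#' @return Tibble with task, variant, method, sizes, max R-hat,
#'   divergences and mean acceptance rate.
#' @export
glance.phenodyn_fit <- function(x, ...) {
  tibble(task = x$task, variant = x$variant, method = x$method,
         n_participants = length(x$participants), n_sessions = nrow(x$obs),
         chains = x$chains, iter_sampling = x$iter_sampling,
         max_rhat = max(x$diagnostics$rhat), divergences = x$divergences,
         accept_rate = x$accept_rate)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
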