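#' Parameter registry for the seven-task computational phenotype
#'
#' Each task model exposes a small set of free parameters. Hierarchical
#' modelling operates in an unconstrained space; each parameter carries a
#' bijective transform linking the two spaces:
#' \itemize{
#'   \item `log` for strictly positive parameters (effect sizes, noise and
#'     threshold magnitudes and their set-size slopes, DDM boundary,
#'     non-decision time and drift coefficient, risk attitude, inverse
#'     temperatures, discount rate, Weber fraction);
#'   \item `logit` for unit-interval parameters (learning rate, lapse rate);
#'   \item `identity` for sign-free parameters (Go bias, Pavlovian bias,
#'     bandit regression weights).
#' }
#'
#' @param task One of [task_codes()].
#' @return A tibble with columns `parameter`, `transform`, `label`.
#' @examples
#' task_params("gng")
#' @export
task_params <- function(task) {
  check_task(task)
  reg <- list(
    gng = tibble(
      parameter = c("b", "pi", "eps", "rho_rp", "rho_neut", "xi"),
      transform = c("identity", "identity", "logit", "log", "log", "logit"),
      label = c("Go bias", "Pavlovian bias", "learning rate",
                "effective reward/punishment size", "effective neutral size",
                "lapse rate")
    ),
    cd = tibble(
      parameter = c("sigma0", "theta0", "sigma_slope", "theta_slope"),
      transform = rep("log", 4),
      label = c("encoding noise (intercept)", "detection threshold (intercept)",
                "noise slope with set size", "threshold slope with set size")
    ),
    rdm = tibble(
      parameter = c("alpha", "tau", "delta"),
      transform = rep("log", 3),
      label = c("boundary separation", "non-decision time (s)",
                "drift coefficient")
    ),
    lt = tibble(
      parameter = c("rho_risk", "beta"),
      transform = c("log", "log"),
      label = c("risk attitude", "inverse temperature")
    ),
    itc = tibble(
      parameter = c("k", "beta"),
      transform = c("log", "log"),
      label = c("discount rate (1/day)", "inverse temperature")
    ),
    tab = tibble(
      parameter = c("w_V", "w_RU", "w_sTU"),
      transform = rep("identity", 3),
      label = c("value-difference weight", "relative-uncertainty weight",
                "signed total-uncertainty weight")
    ),
    nc = tibble(
      parameter = "w",
      transform = "log",
      label = "Weber fraction"
    )
  )
  reg[[task]]
}

transform_of <- function(task, parameter) {
  info <- task_params(task)
  tr <- info$transform[match(parameter, info$parameter)]
  if (anyNA(tr)) abort(paste0("unknown parameter for task ", task))
  tr
}

#' Map parameter values between constrained and unconstrained space
#'
#' `constrain()` maps unconstrained (sampling-space) values to the model's
#' native space; `unconstrain()` is its exact inverse.
#'
#' @param x Numeric vector of values.
#' @param transform One of `"log"`, `"logit"`, `"identity"` (recycled).
#' @return Numeric vector.
#' @export
constrain <- function(x, transform) {
  transform <- rep_len(transform, length(x))
  out <- x
  out[transform == "log"] <- exp(x[transform == "log"])
  out[transform == "logit"] <- logistic(x[transform == "logit"])
  out
}

#' @rdname constrain
#' @export
unconstrain <- function(x, transform) {
  transform <- rep_len(transform, length(x))
  out <- x
  out[transform == "log"] <- log(x[transform == "log"])
  lg <- transform == "logit"
  out[lg] <- log(x[lg] / (1 - x[lg]))
  out
}

# Constrain a named unconstrained parameter vector for one task; returns a
# named list usable by the task likelihoods.
constrain_params <- function(task, theta) {
  info <- task_params(task)
  stopifnot(length(theta) == nrow(info))
  v <- constrain(as.numeric(theta[info$parameter]), info$transform)
  as.list(setNames(v, info$parameter))
}

unconstrain_params <- function(task, params) {
  info <- task_params(task)
  v <- unconstrain(as.numeric(params[info$parameter]), info$transform)
  setNames(v, info$parameter)
}
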