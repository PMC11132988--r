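#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom sd median quantile
#'   optim optimize approx prcomp cor var complete.cases setNames aggregate
#' @importFrom utils head tail
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
NULL

logistic <- function(x) 1 / (1 + exp(-x))

log1p_exp <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 35, x, log1p(exp(x)))
}

#' Seven-task battery task codes
#'
#' @return Character vector of the seven task codes: `gng` (Go/No-go), `cd`
#'   (change detection), `rdm` (random dot motion), `lt` (lottery ticket),
#'   `itc` (intertemporal choice), `tab` (two-armed bandit), `nc`
#'   (numerosity comparison).
#' @export
task_codes <- function() c("gng", "cd", "rdm", "lt", "itc", "tab", "nc")

check_task <- function(task) {
  if (!is.character(task) || length(task) != 1 || !task %in% task_codes()) {
    abort(paste0("`task` must be one of: ", paste(task_codes(), collapse = ", ")))
  }
  task
}

# Derive a reproducible child seed below 2^31 from a parent seed and a tag.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
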