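#' Default task designs for the weekly battery
#'
#' Returns the per-session design specification of one task: block/trial
#' structure, stimulus contingencies and reward distributions. The defaults
#' follow the battery's printed designs (Go/No-go: 3 blocks of 80 trials with
#' an 80/20 outcome contingency; change detection: 5 blocks of 40 trials with
#' set sizes 3/4/6/8 plus a multiple-target block; random dot motion: 4
#' blocks of 96 trials at coherences 0.05/0.10/0.35/0.50; lottery ticket: 3
#' blocks of 10 trials at expected-value scales of roughly $2/$50/$200;
#' intertemporal choice: a 27-item menu; two-armed bandit: 30 blocks of 10
#' trials with block-wise reward means and variances; numerosity comparison:
#' 160 trials). Quantities the source battery leaves to configuration
#' (bandit reward distributions, the exact intertemporal menu) are fields of
#' this list and can be overridden.
#'
#' @param task One of [task_codes()].
#' @return A named list of design fields; `n_trials_session` gives the
#'   total trial count per weekly session.
#' @export
task_design <- function(task) {
  check_task(task)
  switch(task,
    gng = list(
      n_blocks = 3, trials_per_block = 80, n_stimuli = 4,
      conditions = c("gw", "gal", "ngw", "ngal"),
      p_contingent = 0.8,
      n_trials_session = 240
    ),
    cd = list(
      n_blocks = 5, trials_per_block = 40,
      set_sizes = c(3, 4, 6, 8, 8),          # block 5 is the multiple-target block
      multi_block = 5, multi_changes = 0:4,  # 0..4 items change in block 5
      p_change = 0.5,
      n_trials_session = 200
    ),
    rdm = list(
      n_blocks = 4, trials_per_block = 96,
      coherences = c(0.05, 0.10, 0.35, 0.50),
      deadline_s = 1.5,
      n_trials_session = 384
    ),
    lt = list(
      n_blocks = 3, trials_per_block = 10,
      ev_scales = c(2, 50, 200),
      p_hi = seq(0.1, 1.0, by = 0.1),
      # ticket shape follows the battery's printed example at EV scale 1:
      # safe {p: 1.00, 1-p: 0.80}, risky {p: 1.925, 1-p: 0.05}
      safe_hi = 1.00, safe_lo = 0.80, risky_hi = 1.925, risky_lo = 0.05,
      n_trials_session = 30
    ),
    itc = list(
      amounts_later = c(10, 25, 50),
      delays_days = c(7, 30, 90),
      now_fracs = c(0.4, 0.6, 0.8),
      n_trials_session = 27
    ),
    tab = list(
      n_blocks = 30, trials_per_block = 10,
      conditions = c("SS", "RR", "RS", "SR"),
      block_mean_sd = 10,          # s.d. of the per-block arm means
      risky_sds = c(2, 4, 6),      # risky-arm outcome s.d., cycled over blocks
      kalman = list(m0 = 0, s02 = 100, tau_R2 = 16, tau_S2 = 1e-6),
      n_trials_session = 300
    ),
    nc = list(
      n_trials = 160, count_range = c(5, 50),
      n_trials_session = 160
    )
  )
}

# canonical extra columns per task (beyond the shared keys)
task_schema <- function(task) {
  shared <- c("participant_id", "task", "week", "block", "trial")
  extra <- switch(task,
    gng = c("condition", "stimulus", "response", "rt_ms", "outcome", "correct"),
    cd  = c("set_size", "n_changed", paste0("d", 1:8), "response", "rt_ms", "correct"),
    rdm = c("coherence", "response", "rt_ms"),
    lt  = c("p_hi", "safe_hi", "safe_lo", "risky_hi", "risky_lo", "response", "rt_ms"),
    itc = c("amount_now", "amount_later", "delay_days", "response", "rt_ms"),
    tab = c("condition", "arm1_label", "arm2_label", "response", "outcome", "rt_ms"),
    nc  = c("a1", "a2", "response", "rt_ms")
  )
  c(shared, extra)
}
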