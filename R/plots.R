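#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_violin
#'   geom_errorbar geom_hline facet_wrap labs theme_minimal autoplot
NULL

#' Plot posterior summaries of a hierarchical fit
#'
#' Group-level posterior means with credible intervals per parameter and
#' term.
#'
#' @param object A `phenodyn_fit`.
#' @param ... Passed to [tidy.phenodyn_fit()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phenodyn_fit <- function(object, ...) {
  td <- tidy(object, ...)
  ggplot(td, aes(x = .data$term, y = .data$estimate)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                  width = 0.2) +
    facet_wrap(~.data$parameter, scales = "free_y") +
    labs(title = paste0(object$task, " (", object$variant, " model)"),
         x = NULL, y = "posterior estimate") +
    theme_minimal()
}

#' Plot bootstrapped ICC distributions
#'
#' Violin plot of the bootstrap ICC distribution per parameter, in the
#' style of stability figures: medians marked, conventional
#' interpretation bands at 0.5/0.75/0.9.
#'
#' @param icc_tbl Tibble with columns `parameter` and a list- or
#'   long-format `boot` column, or a named list of `icc_result` objects.
#' @return A ggplot object.
#' @export
plot_icc <- function(icc_tbl) {
  if (is.list(icc_tbl) && !is.data.frame(icc_tbl)) {
    icc_tbl <- bind_rows(lapply(names(icc_tbl), function(nm) {
      tibble(parameter = nm, boot = icc_tbl[[nm]]$boot)
    }))
  }
  ggplot(icc_tbl, aes(x = .data$parameter, y = .data$boot)) +
    geom_hline(yintercept = c(0.5, 0.75, 0.9), linetype = "dashed",
               colour = "grey70") +
    geom_violin(fill = "steelblue", alpha = 0.6) +
    labs(x = NULL, y = "bootstrapped ICC(2,1)") +
    theme_minimal()
}

#' Plot a posterior predictive check
#'
#' Observed versus predicted condition-level summary statistics.
#'
#' @param ppc Output of [run_ppc()].
#' @return A ggplot object.
#' @export
plot_ppc <- function(ppc) {
  long <- tidyr::pivot_longer(ppc, c("observed", "predicted"),
                              names_to = "source", values_to = "value")
  ggplot(long, aes(x = .data$condition, y = .data$value,
                   colour = .data$source, group = .data$source)) +
    geom_point() + geom_line() +
    labs(x = NULL, y = "summary statistic") +
    theme_minimal()
}

#' Plot weekly state series
#'
#' Valence and arousal trajectories per participant.
#'
#' @param states Output of [normalize_states()].
#' @param participants Optional subset of participant ids.
#' @return A ggplot object.
#' @export
plot_states <- function(states, participants = NULL) {
  if (!is.null(participants)) {
    states <- filter(states, .data$participant_id %in% participants)
  }
  long <- tidyr::pivot_longer(states, c("valence", "arousal"),
                              names_to = "component", values_to = "score")
  ggplot(long, aes(x = .data$week, y = .data$score,
                   colour = .data$component)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~.data$participant_id) +
    labs(x = "week", y = "state score (within-participant [-1, 1])") +
    theme_minimal()
}

#' Plot relative contributions of the dynamic sources
#'
#' Box-style summary of per-participant relative contributions per
#' parameter and term.
#'
#' @param rc Output of [relative_contributions()].
#' @return A ggplot object.
#' @export
plot_relative_contributions <- function(rc) {
  ggplot(rc, aes(x = .data$term, y = .data$rc)) +
    ggplot2::geom_boxplot(fill = "darkseagreen", alpha = 0.7) +
    facet_wrap(~.data$parameter) +
    labs(x = NULL, y = "relative contribution") +
    theme_minimal()
}
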