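#' Read and validate a trial table
#'
#' Trial files are UTF-8 comma-separated CSV with '.' decimals and literal
#' `NA` for missing values, one file per task. The header must contain the
#' task's documented schema (see [task_schema_columns()]); rows violating
#' the shared invariants (week outside 1..12, negative RT, duplicate
#' (week, block, trial) within participant) raise a validation error naming
#' the offending rows.
#'
#' @param path CSV file path.
#' @param task One of [task_codes()].
#' @return A validated trial tibble.
#' @export
load_trials <- function(path, task) {
  check_task(task)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tt <- readr::read_csv(path, show_col_types = FALSE, na = "NA", progress = FALSE)
  need <- task_schema(task)
  miss <- setdiff(need, names(tt))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing columns for task ", task, ": ",
                 paste(miss, collapse = ", ")))
  }
  # all-missing columns parse as logical; restore the schema types
  char_cols <- c("participant_id", "task",
                 if (task == "gng") c("condition", "outcome"),
                 if (task == "tab") c("condition", "arm1_label", "arm2_label"))
  for (cc in need) {
    if (is.logical(tt[[cc]]) && all(is.na(tt[[cc]]))) {
      tt[[cc]] <- if (cc %in% char_cols) as.character(tt[[cc]]) else
        as.numeric(tt[[cc]])
    }
  }
  validate_trials(tt, task)
}

#' @rdname load_trials
#' @param trials Trial tibble to write.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "NA")
  invisible(path)
}

#' Documented per-task column schema
#' @inheritParams load_trials
#' @return Character vector of required column names.
#' @export
task_schema_columns <- function(task) task_schema(check_task(task))

#' Validate a trial table against the shared invariants
#'
#' @param trials Trial tibble.
#' @inheritParams load_trials
#' @return The tibble, invisibly coerced to canonical types; errors name
#'   offending row numbers.
#' @export
validate_trials <- function(trials, task) {
  check_task(task)
  if (nrow(trials) == 0) return(as_tibble(trials))
  bad_week <- which(!is.na(trials$week) & (trials$week < 1 | trials$week > 12))
  if (length(bad_week) > 0) {
    abort(paste0("validation error: week outside 1..12 in rows ",
                 paste(head(bad_week, 5), collapse = ", ")))
  }
  if ("rt_ms" %in% names(trials)) {
    bad_rt <- which(!is.na(trials$rt_ms) & trials$rt_ms < 0)
    if (length(bad_rt) > 0) {
      abort(paste0("validation error: negative rt_ms in rows ",
                   paste(head(bad_rt, 5), collapse = ", ")))
    }
  }
  key <- paste(trials$participant_id, trials$week, trials$block, trials$trial)
  if (anyDuplicated(key) > 0) {
    abort(paste0("validation error: duplicate (week, block, trial) key in rows ",
                 paste(head(which(duplicated(key)), 5), collapse = ", ")))
  }
  mutate(as_tibble(trials), week = as.integer(.data$week),
         block = as.integer(.data$block), trial = as.integer(.data$trial))
}

#' Read and write the survey table
#'
#' Long format: `participant_id`, `week` (1..12), `day` (1..3), `item_id`
#' (1..36; item 34 is free text and excluded from numeric analysis),
#' `response`.
#'
#' @param path CSV file path.
#' @return Survey tibble.
#' @export
load_survey <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tt <- readr::read_csv(path, show_col_types = FALSE, na = "NA", progress = FALSE)
  need <- c("participant_id", "week", "day", "item_id", "response")
  miss <- setdiff(need, names(tt))
  if (length(miss) > 0) {
    abort(paste0("schema error: missing survey columns: ",
                 paste(miss, collapse = ", ")))
  }
  key <- paste(tt$participant_id, tt$week, tt$day, tt$item_id)
  if (anyDuplicated(key) > 0) abort("duplicate survey responses for one item")
  as_tibble(tt)
}

#' @rdname load_survey
#' @param survey Survey tibble to write.
#' @export
write_survey <- function(survey, path) {
  readr::write_csv(survey, path, na = "NA")
  invisible(path)
}

#' Apply the longitudinal inclusion rule
#'
#' A participant is included for a task iff they have at least `min_weeks`
#' weeks of data and no run of more than `max_gap` consecutive missing
#' weeks. By default gaps are counted between the first and last observed
#' week; `edge_gaps = TRUE` also counts leading/trailing missing runs
#' within weeks 1..12.
#'
#' @param trials Trial tibble (any single task or several; grouped by
#'   `participant_id` x `task`).
#' @param min_weeks Minimum number of observed weeks (default 6).
#' @param max_gap Longest tolerated run of consecutive missing weeks
#'   (default 3).
#' @param edge_gaps Count leading/trailing missing runs too?
#' @param weeks_total Number of calendar weeks in the study (default 12).
#' @return Inclusion report tibble: `participant_id`, `task`,
#'   `n_weeks_present`, `max_consecutive_missing`, `included`,
#'   `exclusion_reason`.
#' @export
apply_inclusion <- function(trials, min_weeks = 6, max_gap = 3,
                            edge_gaps = FALSE, weeks_total = 12) {
  if (nrow(trials) == 0) abort("empty trial table")
  trials |>
    distinct(.data$participant_id, .data$task, .data$week) |>
    group_by(.data$participant_id, .data$task) |>
    summarise(
      n_weeks_present = dplyr::n_distinct(.data$week),
      max_consecutive_missing = max_missing_run(.data$week, edge_gaps, weeks_total),
      .groups = "drop") |>
    mutate(
      exclusion_reason = dplyr::case_when(
        .data$n_weeks_present < min_weeks ~ "too_few_weeks",
        .data$max_consecutive_missing > max_gap ~ "gap_too_long",
        TRUE ~ "none"),
      included = .data$exclusion_reason == "none")
}

max_missing_run <- function(weeks, edge_gaps = FALSE, weeks_total = 12) {
  weeks <- sort(unique(weeks))
  lo <- if (edge_gaps) 1L else min(weeks)
  hi <- if (edge_gaps) as.integer(weeks_total) else max(weeks)
  present <- lo:hi %in% weeks
  if (all(present)) return(0L)
  r <- rle(!present)
  max(c(0L, r$lengths[r$values]))
}

#' Apply the task-specific behavioural exclusions
#'
#' Go/No-go participants with study-average accuracy below 0.55 are flagged
#' as non-learners (`gng_nonlearner`); lottery participants choosing the
#' same option on strictly more than 80% of all trials are flagged
#' `lt_one_sided`. Other tasks carry no behavioural exclusion.
#'
#' @param trials Trial tibble containing `gng` and/or `lt` rows.
#' @param gng_accuracy_min Non-learner threshold (default 0.55).
#' @param lt_one_sided_max One-sidedness threshold (default 0.8, strict).
#' @return Inclusion report tibble with `exclusion_reason` in
#'   `none/gng_nonlearner/lt_one_sided`.
#' @export
apply_task_exclusions <- function(trials, gng_accuracy_min = 0.55,
                                  lt_one_sided_max = 0.8) {
  out <- list()
  gng <- filter(trials, .data$task == "gng")
  if (nrow(gng) > 0) {
    out$gng <- gng |>
      group_by(.data$participant_id, .data$task) |>
      summarise(stat = mean(.data$correct, na.rm = TRUE), .groups = "drop") |>
      mutate(exclusion_reason = ifelse(.data$stat < gng_accuracy_min,
                                       "gng_nonlearner", "none"))
  }
  lt <- filter(trials, .data$task == "lt")
  if (nrow(lt) > 0) {
    out$lt <- lt |>
      group_by(.data$participant_id, .data$task) |>
      summarise(stat = max(mean(.data$response, na.rm = TRUE),
                           1 - mean(.data$response, na.rm = TRUE)),
                .groups = "drop") |>
      mutate(exclusion_reason = ifelse(.data$stat > lt_one_sided_max,
                                       "lt_one_sided", "none"))
  }
  if (length(out) == 0) return(tibble(participant_id = character(),
                                      task = character(), stat = numeric(),
                                      exclusion_reason = character(),
                                      included = logical()))
  bind_rows(out) |> mutate(included = .data$exclusion_reason == "none")
}
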