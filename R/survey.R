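#' Derive valence and arousal state scores from the personal survey
#'
#' Implements the survey dimensionality reduction: item 34 (free text) is
#' excluded; responses are arranged as one row per observed
#' (participant, week, day) session and one column per item; each column is
#' z-scored across all available rows (missing sessions ignored); rows with
#' any missing item are dropped; PCA is run on the z-scored matrix and the
#' top two component scores retained. The first component is interpreted as
#' affective valence and the second as affective arousal. Scores are then
#' averaged over the days of each week, and missing weeks are linearly
#' interpolated per participant (after the PCA, never before).
#'
#' Sign convention: if `valence_items` (ids of positive-emotion items) is
#' given, PC1 is oriented so their mean loading is positive, and similarly
#' PC2 with `arousal_items`; otherwise each component is oriented so its
#' largest-magnitude loading is positive, which is deterministic for a
#' given table.
#'
#' @param survey Survey tibble (`participant_id`, `week`, `day`,
#'   `item_id`, `response`).
#' @param valence_items,arousal_items Optional integer item ids used to
#'   orient the components.
#' @param exclude_items Item ids excluded from the numeric analysis
#'   (default 34, the free-text item).
#' @return A `state_series` tibble: `participant_id`, `week`,
#'   `valence_raw`, `arousal_raw`, `interpolated`; attributes `loadings`
#'   (item x PC tibble) and `explained_variance` (fractions for PC1, PC2).
#' @export
compute_state_components <- function(survey, valence_items = NULL,
                                     arousal_items = NULL,
                                     exclude_items = 34) {
  sv <- filter(survey, !.data$item_id %in% exclude_items)
  if (dplyr::n_distinct(sv$item_id) < 2) abort("need at least 2 survey items")
  wide <- sv |>
    tidyr::pivot_wider(id_cols = c("participant_id", "week", "day"),
                       names_from = "item_id", values_from = "response",
                       names_prefix = "item")
  items <- setdiff(names(wide), c("participant_id", "week", "day"))
  x <- as.matrix(wide[items])
  keep_rows <- complete.cases(x)
  xc <- x[keep_rows, , drop = FALSE]
  if (nrow(xc) < 3) abort("need at least 3 complete survey sessions")
  sds <- apply(xc, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant survey items: ",
                paste(items[sds == 0], collapse = ", ")))
    xc <- xc[, sds > 0, drop = FALSE]
    items <- items[sds > 0]
  }
  z <- scale(xc)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]

  orient <- function(j, ids) {
    if (!is.null(ids)) {
      sel <- items %in% paste0("item", ids)
      if (any(sel)) return(sign(mean(load[sel, j])))
    }
    sign(load[which.max(abs(load[, j])), j])
  }
  s1 <- orient(1, valence_items); s2 <- orient(2, arousal_items)
  s1 <- ifelse(s1 == 0, 1, s1); s2 <- ifelse(s2 == 0, 1, s2)
  scores[, 1] <- s1 * scores[, 1]; load[, 1] <- s1 * load[, 1]
  scores[, 2] <- s2 * scores[, 2]; load[, 2] <- s2 * load[, 2]

  sess <- wide[keep_rows, c("participant_id", "week", "day")]
  sess$pc1 <- scores[, 1]; sess$pc2 <- scores[, 2]

  weekly <- sess |>
    group_by(.data$participant_id, .data$week) |>
    summarise(valence_raw = mean(.data$pc1), arousal_raw = mean(.data$pc2),
              .groups = "drop")

  # linear interpolation of missing weeks per participant (after PCA)
  full <- weekly |>
    group_by(.data$participant_id) |>
    tidyr::complete(week = tidyr::full_seq(.data$week, 1)) |>
    arrange(.data$participant_id, .data$week) |>
    mutate(interpolated = is.na(.data$valence_raw)) |>
    mutate(valence_raw = interp_series(.data$week, .data$valence_raw),
           arousal_raw = interp_series(.data$week, .data$arousal_raw)) |>
    ungroup()

  single <- weekly |> count(.data$participant_id) |> filter(.data$n < 2)
  if (nrow(single) > 0) {
    warn(paste0("participants with < 2 observed survey weeks (no ",
                "interpolation possible): ",
                paste(single$participant_id, collapse = ", ")))
  }
  structure(full, loadings = tibble(item = items,
                                    PC1 = load[, 1], PC2 = load[, 2]),
            explained_variance = expl[1:2],
            class = c("state_series", class(full)))
}

interp_series <- function(week, y) {
  if (sum(!is.na(y)) < 2) return(y)
  approx(week[!is.na(y)], y[!is.na(y)], xout = week, rule = 2)$y
}

#' Normalize state scores within participant to [-1, 1]
#'
#' Affine map per participant and component sending the minimum over the
#' participant's sessions to -1 and the maximum to +1; constant series map
#' to 0. This matches the state predictors entering the dynamic model.
#'
#' @param states Output of [compute_state_components()] (or any tibble
#'   with `participant_id`, `week`, `valence_raw`, `arousal_raw`).
#' @return The tibble with `valence` and `arousal` columns in `[-1, 1]`.
#' @export
normalize_states <- function(states) {
  states |>
    group_by(.data$participant_id) |>
    mutate(valence = minmax_pm1(.data$valence_raw),
           arousal = minmax_pm1(.data$arousal_raw)) |>
    ungroup()
}

minmax_pm1 <- function(x) {
  lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  if (!is.finite(lo) || hi - lo < 1e-12) return(ifelse(is.na(x), NA_real_, 0))
  2 * (x - lo) / (hi - lo) - 1
}
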