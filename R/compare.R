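#' Compare correct vs. alternative maze representations per participant
#'
#' For each participant and test session, the judged pointing directions
#' on the trials flagged as bimodal are scored against the true directions
#' of two candidate representations — the correct layout and an edited
#' alternative layout — and the representation with the smaller mean
#' absolute angular error is declared the better fit. Errors are computed
#' per record and then averaged. Ties prefer the correct representation
#' (conservative toward the null). When the alternative wins, the
#' error-reduction fraction `1 - mean_alt / mean_correct` is reported.
#'
#' @param records Data frame of pointing records with columns
#'   `participant`, `session`, `origin`, `target`, `judged`.
#' @param bimodal_trials Data frame with columns `origin`, `target`: the
#'   ordered trials whose pooled directions were flagged bimodal (see
#'   [select_modality()]).
#' @param correct,alternative [maze_layout()] objects sharing location
#'   ids; every bimodal trial must be resolvable (non-coincident) in both.
#' @return A tibble with one row per participant x session: `n_trials`,
#'   `mean_error_correct`, `mean_error_alternative`, `better_fit`
#'   (`"correct"`/`"alternative"`), `error_reduction` (fraction in
#'   `[0, 1)` when the alternative wins, `NA` otherwise). Participants
#'   with no records on bimodal trials are excluded with a message.
#' @export
compare_models <- function(records, bimodal_trials, correct, alternative) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("participant", "session", "origin", "target", "judged")
                %in% names(records)),
            inherits(correct, "maze_layout"),
            inherits(alternative, "maze_layout"))
  bimodal_trials <- tibble::as_tibble(bimodal_trials)[, c("origin", "target")]
  bimodal_trials <- dplyr::distinct(bimodal_trials)
  if (!nrow(bimodal_trials)) stop("bimodal_trials is empty")

  dirs <- bimodal_trials
  dirs$dir_correct <- vapply(seq_len(nrow(dirs)), function(i) {
    true_direction(correct, dirs$origin[i], dirs$target[i])
  }, numeric(1))
  dirs$dir_alternative <- vapply(seq_len(nrow(dirs)), function(i) {
    true_direction(alternative, dirs$origin[i], dirs$target[i])
  }, numeric(1))

  used <- dplyr::inner_join(records, dirs, by = c("origin", "target"))
  dropped <- setdiff(unique(records$participant), unique(used$participant))
  if (length(dropped)) {
    message(length(dropped),
            " participant(s) had no records on bimodal trials and were excluded: ",
            paste(dropped, collapse = ", "))
  }
  if (!nrow(used)) stop("no records fall on the given bimodal trials")

  used |>
    dplyr::mutate(
      err_c = angular_error(.data$judged, .data$dir_correct),
      err_a = angular_error(.data$judged, .data$dir_alternative)
    ) |>
    dplyr::group_by(.data$participant, .data$session) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_error_correct = mean(.data$err_c),
      mean_error_alternative = mean(.data$err_a),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      better_fit = ifelse(.data$mean_error_alternative <
                            .data$mean_error_correct,
                          "alternative", "correct"),
      error_reduction = ifelse(
        .data$better_fit == "alternative",
        1 - .data$mean_error_alternative / .data$mean_error_correct,
        NA_real_)
    )
}

#' Aggregate representation preference over the cohort
#'
#' Summarizes [compare_models()] results per perspective group x SOD level
#' x session cell: the percentage of participants for whom the alternative
#' representation fit better, and the mean error-reduction fraction among
#' those participants. Cells with no participants are reported as missing
#' (`n = 0`, `NA` percentage), not as zero. Overall per-session
#' percentages are reported alongside.
#'
#' @param comparisons Output of [compare_models()].
#' @param profiles Data frame with columns `participant`, `group`, and
#'   `sod_level` used to label the comparisons.
#' @return An object of class `preference_summary`: a list with `cells`
#'   (group x SOD x session tibble) and `overall` (per-session tibble).
#' @export
aggregate_preference <- function(comparisons, profiles) {
  comparisons <- tibble::as_tibble(comparisons)
  profiles <- tibble::as_tibble(profiles)
  stopifnot(all(c("participant", "session", "better_fit", "error_reduction")
                %in% names(comparisons)),
            all(c("participant", "group", "sod_level") %in% names(profiles)))
  if (!nrow(comparisons)) stop("no comparisons to aggregate")
  lab <- dplyr::inner_join(
    comparisons,
    dplyr::distinct(profiles[, c("participant", "group", "sod_level")]),
    by = "participant")
  if (!nrow(lab)) stop("no comparison rows matched the profiles")

  cell_summary <- function(df) {
    dplyr::summarise(
      df,
      n = dplyr::n(),
      pct_alternative = 100 * mean(.data$better_fit == "alternative"),
      mean_error_reduction =
        if (any(df$better_fit == "alternative")) {
          mean(.data$error_reduction[.data$better_fit == "alternative"])
        } else {
          NA_real_
        },
      .groups = "drop")
  }
  cells <- lab |>
    dplyr::group_by(.data$group, .data$sod_level, .data$session) |>
    cell_summary() |>
    tidyr::complete(
      group = unique(lab$group),
      sod_level = unique(lab$sod_level),
      session = unique(lab$session),
      fill = list(n = 0L)) |>
    dplyr::arrange(.data$group, .data$sod_level, .data$session)
  overall <- lab |>
    dplyr::group_by(.data$session) |>
    cell_summary()
  structure(list(cells = cells, overall = overall),
            class = "preference_summary")
}

#' @export
print.preference_summary <- function(x, ...) {
  cat("<preference_summary>\n")
  cat("Per-cell percentage preferring the alternative representation:\n")
  print(x$cells, n = Inf)
  cat("Overall per session:\n")
  print(x$overall)
  invisible(x)
}
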