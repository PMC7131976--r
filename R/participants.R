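#' Raw TLX workload score
#'
#' Overall mental-workload estimate from the six task-load subscale
#' ratings (mental, physical, and temporal demand, performance, effort,
#' frustration): their arithmetic mean.
#'
#' @param items Numeric vector of exactly six ratings.
#' @param scale Rating scale bounds, default the 10-point scale
#'   `c(1, 10)`.
#' @return The mean of the six ratings.
#' @examples
#' raw_tlx(c(1, 2, 3, 4, 5, 6)) # 3.5
#' @export
raw_tlx <- function(items, scale = c(1, 10)) {
  if (length(items) != 6) stop("Raw TLX requires exactly six subscale ratings")
  if (anyNA(items) || any(items < scale[1] | items > scale[2])) {
    stop(sprintf("ratings must lie within the scale bounds [%g, %g]",
                 scale[1], scale[2]))
  }
  mean(items)
}

#' Exclude participants by visible pointing error
#'
#' Visible pointing trials (origin and target intervisible) serve as an
#' accuracy reference: participants whose average visible pointing error
#' exceeds Q3 + 1.5 * IQR of the pooled distribution are flagged as
#' having failed the reference task and excluded. Quartiles use R's
#' default linear-interpolation rule (type 7). The threshold is
#' affine-equivariant: adding a constant to all errors shifts Q3 and the
#' threshold alike and leaves the excluded set unchanged.
#'
#' @param errors Named numeric vector (names = participant ids) of
#'   per-participant mean visible errors, or a data frame with columns
#'   `participant` and `error`.
#' @return Character vector of excluded participant ids (those strictly
#'   above the threshold), with the threshold attached as an attribute.
#' @examples
#' exclude_by_visible_error(c(a = 1, b = 2, c = 3, d = 4, e = 100))
#' @export
exclude_by_visible_error <- function(errors) {
  if (is.data.frame(errors)) {
    stopifnot(all(c("participant", "error") %in% names(errors)))
    errors <- setNames(errors$error, errors$participant)
  }
  if (length(errors) < 4) {
    stop("need at least 4 participants for stable quartiles")
  }
  q <- quantile(errors, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  out <- names(errors)[errors > thr]
  attr(out, "threshold") <- thr
  out
}

#' Median split of sense-of-direction scores
#'
#' Splits participants into low and high sense-of-direction (SOD) strata
#' at the pooled median, within each pool (by default the experiment
#' pool, i.e. both perspective groups of an experiment together). Scores
#' strictly below the median are `"low"`, strictly above are `"high"`;
#' participants tied at the median are assigned deterministically in
#' participant-id order so that the two strata differ in size by at most
#' one (a warning reports when ties had to be broken). With an even
#' number of distinct scores this yields exactly equal halves.
#'
#' @param profiles Data frame with columns `participant` and `sod_score`,
#'   plus the pooling column.
#' @param pool Name of the column defining the split pools (default
#'   `"experiment"`); use a constant column to split the whole table at
#'   once.
#' @return `profiles` with an added/overwritten `sod_level` column
#'   (`"low"`/`"high"`).
#' @export
sod_median_split <- function(profiles, pool = "experiment") {
  profiles <- tibble::as_tibble(profiles)
  stopifnot(all(c("participant", "sod_score") %in% names(profiles)))
  if (!pool %in% names(profiles)) {
    stop(sprintf("pooling column '%s' not found", pool))
  }
  split_one <- function(df) {
    n <- nrow(df)
    if (n < 2) stop("each pool needs at least 2 participants")
    med <- median(df$sod_score)
    lev <- ifelse(df$sod_score < med, "low",
                  ifelse(df$sod_score > med, "high", NA))
    ties <- which(is.na(lev))
    if (length(ties)) {
      n_low_needed <- floor(n / 2) - sum(lev == "low", na.rm = TRUE)
      ties <- ties[order(df$participant[ties])]
      take <- seq_along(ties) <= max(n_low_needed, 0)
      lev[ties[take]] <- "low"
      lev[ties[!take]] <- "high"
      if (length(ties) > 1) {
        warning("ties at the median SOD score broken by participant id")
      }
    }
    df$sod_level <- lev
    df
  }
  profiles |>
    dplyr::group_by(.data[[pool]]) |>
    dplyr::group_modify(~ split_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::relocate(dplyr::all_of(pool), .after = dplyr::last_col())
}
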