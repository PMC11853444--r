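#' Pair marrow and plasma VAFs for the same mutations
#'
#' Builds the matched pairs behind the marrow-versus-plasma VAF
#' comparison: one record per mutation key in the union of the two
#' compartments, assigning a VAF of 0 on the side where the mutation was
#' not detected.
#'
#' @param bm_calls,plasma_calls Variant tibbles from the same subject(s)
#'   and nominal timepoint; keys are (subject_id, day, gene, variant_key).
#' @return Tibble with the key columns plus `vaf_bm` and `vaf_plasma`.
#' @export
build_paired_vafs <- function(bm_calls, plasma_calls) {
  key_cols <- c("subject_id", "day", "gene", "variant_key")
  one_side <- function(x, col) {
    if (nrow(x) > 0 && !all(x$compartment == x$compartment[[1]])) {
      stop_cfmrd("each input must come from a single compartment",
                 class = "cfmrd_value_error")
    }
    dup <- x |> count(across(dplyr::all_of(key_cols))) |> filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop_cfmrd(paste0("duplicate keys within the ", col, " compartment"),
                 class = "cfmrd_value_error")
    }
    out <- x |> select(dplyr::all_of(key_cols), "vaf")
    names(out)[names(out) == "vaf"] <- paste0("vaf_", col)
    out
  }
  full_join(one_side(bm_calls, "bm"), one_side(plasma_calls, "plasma"),
            by = key_cols) |>
    mutate(vaf_bm = dplyr::coalesce(.data$vaf_bm, 0),
           vaf_plasma = dplyr::coalesce(.data$vaf_plasma, 0))
}

#' Wilcoxon matched-pair signed-rank test on paired VAFs
#'
#' Compares paired per-mutation VAFs between compartments. Zero-difference
#' pairs are dropped (the standard signed-rank convention - relevant here
#' because assigning 0 to undetected mutations creates exact ties whenever
#' a mutation is missing from both sides), mid-ranks are used for tied
#' absolute differences, and the null distribution is exact for up to
#' `exact_max` non-zero tie-free pairs, otherwise a normal approximation
#' with continuity correction.
#'
#' @param pairs Tibble from [build_paired_vafs()] (or any data frame with
#'   `vaf_bm` and `vaf_plasma` columns).
#' @param exact_max Largest n for which the exact distribution is used.
#' @return One-row tibble: `statistic` (V, rank sum of positive
#'   plasma-minus-marrow differences), `n_pairs`, `n_used`, `p_value`,
#'   `method`.
#' @export
wilcoxon_matched_pairs <- function(pairs, exact_max = 25) {
  d <- pairs$vaf_plasma - pairs$vaf_bm
  nz <- d[d != 0]
  if (length(nz) == 0) {
    stop_not_evaluable("all paired differences are zero")
  }
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= exact_max && !ties
  keep <- d != 0 # drop zero pairs up front so the exact path stays available
  wt <- suppressWarnings(
    stats::wilcox.test(pairs$vaf_plasma[keep], pairs$vaf_bm[keep],
                       paired = TRUE, exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(wt$statistic),
    n_pairs = length(d),
    n_used = length(nz),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation with continuity correction"
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1 degrees
#' of freedom; used in this workflow to compare per-subject mutation
#' counts between marrow and plasma testing.
#'
#' @param values Numeric vector, or a list of numeric vectors (one per
#'   group, `group` then ignored).
#' @param group Grouping vector parallel to `values`.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, group = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  if (length(unique(group)) < 2) {
    stop_cfmrd("need at least 2 groups", class = "cfmrd_value_error")
  }
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = length(unique(group)) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, factor(group))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Median and range summary
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `median` (mean of the central pair for an even
#'   count), `min`, `max`, `n`.
#' @examples
#' median_range(c(170, 62, 168, 52, 167, 139))
#' @export
median_range <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop_not_evaluable("no values to summarize")
  tibble(median = stats::median(values), min = min(values), max = max(values),
         n = length(values))
}

#' Overall and relapse-free survival times
#'
#' Overall survival runs from day 0 (completion of the stem-cell infusion)
#' to death; relapse-free survival to the earlier of relapse or death.
#' Subjects without the event are censored at the last follow-up day.
#'
#' @param subjects Subject tibble with `subject_id`, `relapse_day`,
#'   `death_day`, `last_followup_day`.
#' @return Tibble: `subject_id`, `os_days`, `event_os`, `rfs_days`,
#'   `event_rfs`.
#' @export
survival_times <- function(subjects) {
  bad <- !is.na(subjects$relapse_day) & !is.na(subjects$death_day) &
    subjects$relapse_day > subjects$death_day
  if (any(bad)) {
    stop_cfmrd(paste0("relapse_day after death_day for subject(s): ",
                      paste(subjects$subject_id[bad], collapse = ", ")),
               class = "cfmrd_value_error")
  }
  subjects |>
    mutate(
      event_os = !is.na(.data$death_day),
      os_days = if_else(.data$event_os, as.numeric(.data$death_day),
                        as.numeric(.data$last_followup_day)),
      event_rfs = !is.na(.data$relapse_day) | !is.na(.data$death_day),
      rfs_days = if_else(
        .data$event_rfs,
        pmin(as.numeric(.data$relapse_day), as.numeric(.data$death_day), na.rm = TRUE),
        as.numeric(.data$last_followup_day)
      )
    ) |>
    select("subject_id", "os_days", "event_os", "rfs_days", "event_rfs")
}
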