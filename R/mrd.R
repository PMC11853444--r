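#' Geometric mean of variant allele frequencies
#'
#' The per-sample residual-disease burden summary: every somatic mutation
#' detected in a sample contributes its VAF, and the sample is summarized by
#' `exp(mean(log(vaf)))` on the percent scale. Undetected mutations are
#' excluded upstream, never zero-filled (a single zero would annihilate the
#' product and contradict the tabulated values). An empty input returns
#' `NA` - the "not evaluable" (NE) state of a sample with no mutations.
#'
#' @param vafs Numeric vector of VAFs in percent, all > 0.
#' @param digits Decimal places for the reported value (2 matches the
#'   precision of published per-sample summaries). `NULL` skips rounding.
#' @return A single percent value, or `NA_real_` for an empty input.
#' @examples
#' geometric_mean_vaf(c(63.57, 28.71))
#' geometric_mean_vaf(numeric(0))
#' @export
geometric_mean_vaf <- function(vafs, digits = 2) {
  if (length(vafs) == 0) return(NA_real_)
  if (any(is.na(vafs)) || any(vafs <= 0)) {
    stop_cfmrd("all VAFs must be > 0; zero means not detected and must be excluded upstream",
               class = "cfmrd_value_error")
  }
  g <- exp(mean(log(vafs)))
  if (is.null(digits)) g else round_half_up(g, digits)
}

#' Summarize samples as mutation count and GM VAF
#'
#' Aggregates somatic variant calls to one row per (subject, day,
#' compartment) sample: the number of mutations and their geometric-mean
#' VAF (`NA` with status `"NE"` when no mutations were detected).
#'
#' @param calls Somatic variant tibble.
#' @return Tibble with `subject_id`, `day`, `compartment`, `n_mutations`,
#'   `gm_vaf`, `status`.
#' @export
mrd_summarize <- function(calls) {
  calls |>
    group_by(.data$subject_id, .data$day, .data$compartment) |>
    summarise(n_mutations = dplyr::n(),
              gm_vaf = geometric_mean_vaf(.data$vaf),
              .groups = "drop") |>
    mutate(status = if_else(.data$n_mutations == 0, "NE", "ok"))
}

#' Build a longitudinal residual-disease trajectory for one subject
#'
#' Assembles per-timepoint sample aggregates and per-variant VAF series.
#' Three sample states are kept distinct throughout: a tested sample with
#' zero mutations (status `"NE"`, count 0), a sample never taken (status
#' `"ND"`, count `NA`), and a tested sample with mutations (status `"ok"`).
#' `extra_cells` supplies count/GM aggregates for timepoints where only
#' summary-level data exist (no per-gene detail); such samples are marked
#' `gene_level = FALSE` and are used for burden trajectories but not for
#' per-gene clearance calls.
#'
#' @param calls Somatic variant tibble (all subjects or just this one).
#' @param subject A one-row subject tibble, or a subject id string.
#' @param sample_status Optional tibble `subject_id`, `day`, `compartment`,
#'   `status` (`tested`/`ND`), `gene_level` declaring which sample slots
#'   exist. Defaults to the slots observed in `calls` (all gene-level).
#' @param extra_cells Optional tibble of summary-only aggregates
#'   (`subject_id`, `day`, `compartment`, `n_mutations`, `gm_vaf`, `status`).
#' @return An object of class `mrd_trajectory`: list with `subject_id`,
#'   `samples` (per-timepoint aggregates) and `variant_series` (per-variant
#'   VAF series with explicit not-detected gaps, `vaf = NA`).
#' @export
build_trajectory <- function(calls, subject, sample_status = NULL,
                             extra_cells = NULL) {
  if (is.data.frame(subject)) {
    if (nrow(subject) == 0) {
      stop_cfmrd("unknown subject: empty subject record", class = "cfmrd_key_error")
    }
    sid <- subject$subject_id[[1]]
  } else {
    sid <- as.character(subject)
  }
  calls_s <- calls |> filter(.data$subject_id == sid)

  if (is.null(sample_status)) {
    slots <- calls_s |>
      distinct(.data$subject_id, .data$day, .data$compartment) |>
      mutate(status = "tested", gene_level = TRUE)
  } else {
    slots <- sample_status |> filter(.data$subject_id == sid)
  }

  agg <- mrd_summarize(calls_s)
  samples <- slots |>
    left_join(agg |> select(-"status") |> rename(.n = "n_mutations", .gm = "gm_vaf"),
              by = c("subject_id", "day", "compartment")) |>
    mutate(
      n_mutations = case_when(
        .data$status == "ND" ~ NA_integer_,
        .data$gene_level ~ as.integer(dplyr::coalesce(.data$.n, 0L)),
        TRUE ~ NA_integer_
      ),
      gm_vaf = if_else(.data$status == "ND", NA_real_, .data$.gm),
      status = case_when(
        .data$status == "ND" ~ "ND",
        .data$gene_level & dplyr::coalesce(.data$.n, 0L) == 0L ~ "NE",
        TRUE ~ "ok"
      )
    ) |>
    select(-".n", -".gm")

  if (!is.null(extra_cells)) {
    ec <- extra_cells |>
      filter(.data$subject_id == sid) |>
      select("subject_id", "day", "compartment",
             .n_ec = "n_mutations", .gm_ec = "gm_vaf", .status_ec = "status")
    # summary-only aggregates fill slots that lack gene-level data ...
    samples <- samples |>
      left_join(ec, by = c("subject_id", "day", "compartment")) |>
      mutate(
        use_ec = !.data$gene_level & !is.na(.data$.status_ec),
        n_mutations = if_else(.data$use_ec, .data$.n_ec, .data$n_mutations),
        gm_vaf = if_else(.data$use_ec, .data$.gm_ec, .data$gm_vaf),
        status = if_else(.data$use_ec, .data$.status_ec, .data$status)
      ) |>
      select(-".n_ec", -".gm_ec", -".status_ec", -"use_ec")
    # ... and contribute whole samples absent from the status sheet
    extra <- extra_cells |>
      filter(.data$subject_id == sid) |>
      anti_join(samples, by = c("subject_id", "day", "compartment")) |>
      mutate(gene_level = FALSE)
    samples <- bind_rows(samples, extra)
  }
  samples <- samples |> arrange(day_key(.data$day), .data$compartment)

  days_seen <- samples |>
    filter(.data$status != "ND", .data$gene_level) |>
    distinct(.data$day, .data$compartment)
  variant_series <- calls_s |>
    distinct(.data$gene, .data$variant_key) |>
    tidyr::crossing(days_seen) |>
    left_join(calls_s |> select("day", "compartment", "gene", "variant_key", "vaf"),
              by = c("day", "compartment", "gene", "variant_key")) |>
    arrange(.data$gene, .data$variant_key, day_key(.data$day), .data$compartment)

  structure(
    list(subject_id = sid, samples = samples, variant_series = variant_series),
    class = "mrd_trajectory"
  )
}

#' @export
print.mrd_trajectory <- function(x, ...) {
  cat("<mrd_trajectory> subject", x$subject_id, "\n")
  print(x$samples, ...)
  invisible(x)
}

# plasma samples of a trajectory with per-gene data, time-ordered
plasma_gene_samples <- function(trajectory) {
  trajectory$samples |>
    filter(.data$compartment == "plasma", .data$status != "ND", .data$gene_level) |>
    arrange(day_key(.data$day))
}

last_evaluable_plasma_day <- function(trajectory) {
  s <- plasma_gene_samples(trajectory) |> filter(.data$day != "pre")
  if (nrow(s) == 0) return(NA_character_)
  s$day[[nrow(s)]]
}

#' Classify clearance of mutations over the transplant course
#'
#' For each gene (or a supplied subset), decides between:
#' `never_present`, `cleared_pre` (absent from all pre-transplant samples
#' but documented at diagnosis), `cleared_post` (present before transplant,
#' absent at the last evaluable post-transplant plasma timepoint), and
#' `persistent` (present at the last evaluable plasma timepoint). Samples
#' not done (`ND`) are skipped rather than read as negative, so a subject
#' whose final sample was never taken cannot be called cleared on that
#' basis. "Last evaluable wins": a variant absent at an interim timepoint
#' but back at the final one is persistent.
#'
#' @param trajectory An [build_trajectory()] object with a pre timepoint
#'   and at least one post-transplant plasma timepoint.
#' @param genes `"all"` (every gene observed for this subject) or a
#'   character vector of gene symbols.
#' @param diagnosis_genes Optional character vector of genes documented at
#'   diagnosis (used for the `cleared_pre` state; unavailable genes are
#'   classified from the observed samples alone).
#' @return Tibble with `gene`, `status`, `first_cleared_day`.
#' @export
detect_clearance <- function(trajectory, genes = "all", diagnosis_genes = NULL) {
  last_day <- last_evaluable_plasma_day(trajectory)
  if (is.na(last_day)) {
    stop_not_evaluable(paste0("subject ", trajectory$subject_id,
                              ": no evaluable post-transplant plasma sample"))
  }
  observed <- unique(trajectory$variant_series$gene)
  gene_set <- if (identical(genes, "all")) union(observed, diagnosis_genes %||% character(0))
              else unique(genes)

  plasma <- plasma_gene_samples(trajectory)
  pre_any <- trajectory$samples |>
    filter(.data$day == "pre", .data$status != "ND", .data$gene_level)
  series <- trajectory$variant_series

  present_at <- function(g, d, comp = NULL) {
    rows <- series |> filter(.data$gene == g, .data$day == d, !is.na(.data$vaf))
    if (!is.null(comp)) rows <- rows |> filter(.data$compartment == comp)
    nrow(rows) > 0
  }

  purrr::map_dfr(gene_set, function(g) {
    pre_present <- any(vapply(unique(pre_any$day), function(d) present_at(g, d), logical(1)))
    at_dx <- g %in% (diagnosis_genes %||% character(0))
    post_days <- plasma |> filter(.data$day != "pre") |> pull(.data$day)
    present_post <- vapply(post_days, function(d) present_at(g, d, "plasma"), logical(1))

    status <- if (present_at(g, last_day, "plasma")) {
      "persistent"
    } else if (pre_present) {
      "cleared_post"
    } else if (at_dx) {
      "cleared_pre"
    } else if (any(present_post)) {
      # appeared after transplant, gone by the last evaluable sample
      "cleared_post"
    } else {
      "never_present"
    }

    first_cleared <- NA_character_
    if (status %in% c("cleared_post", "cleared_pre")) {
      ever <- c(pre_present, present_post)
      days <- c("pre", post_days)
      last_present_idx <- if (any(ever)) max(which(ever)) else 0L
      after <- days[seq_along(days) > last_present_idx & days != "pre"]
      if (length(after) > 0) first_cleared <- after[[1]]
      if (status == "cleared_pre") first_cleared <- "pre"
    }
    tibble(gene = g, status = status, first_cleared_day = first_cleared)
  })
}

#' Flag an impending relapse from rising burden plus falling chimerism
#'
#' Early relapses in cfDNA surveillance announce themselves as a steep rise
#' in the GM VAF or in the number of detected mutations, together with a
#' falling donor chimerism over the same interval. The flag fires when,
#' between two consecutive post-transplant plasma timepoints, the GM rises
#' at least `fold`-fold or the mutation count rises by at least
#' `count_rise`, and the cfDNA donor chimerism falls by at least `delta`
#' percentage points over that same span.
#'
#' @param trajectory An [build_trajectory()] object with at least two
#'   post-transplant plasma timepoints.
#' @param chimerism Tibble with `subject_id`, `day`, `donor_percent`
#'   (cfDNA-based estimates matching the trajectory's timepoints).
#' @param fold Minimum GM fold-change between consecutive timepoints.
#' @param count_rise Minimum increase in mutation count.
#' @param delta Minimum chimerism fall (percentage points).
#' @return An object of class `relapse_flag`: list with `flag` (logical),
#'   `subject_id` and `evidence` (one row per consecutive-pair interval
#'   with the triggering deltas).
#' @export
flag_impending_relapse <- function(trajectory, chimerism,
                                   fold = 3, count_rise = 3, delta = 2) {
  s <- trajectory$samples |>
    filter(.data$compartment == "plasma", .data$day != "pre", .data$status != "ND") |>
    arrange(day_key(.data$day))
  if (nrow(s) < 2) {
    stop_not_evaluable(paste0("subject ", trajectory$subject_id,
                              ": fewer than 2 post-transplant plasma timepoints"))
  }
  chim <- chimerism |>
    filter(.data$subject_id == trajectory$subject_id) |>
    mutate(day = as.character(.data$day)) |>
    select("day", "donor_percent")
  s <- s |> left_join(chim, by = "day")

  evidence <- tibble(
    day_from = s$day[-nrow(s)], day_to = s$day[-1],
    gm_from = s$gm_vaf[-nrow(s)], gm_to = s$gm_vaf[-1],
    n_from = s$n_mutations[-nrow(s)], n_to = s$n_mutations[-1],
    chim_from = s$donor_percent[-nrow(s)], chim_to = s$donor_percent[-1]
  ) |>
    mutate(
      gm_fold = .data$gm_to / .data$gm_from,
      gm_trigger = !is.na(.data$gm_fold) & .data$gm_fold >= fold,
      count_trigger = !is.na(.data$n_to - .data$n_from) &
        (.data$n_to - .data$n_from) >= count_rise,
      chimerism_falling = !is.na(.data$chim_to - .data$chim_from) &
        (.data$chim_to - .data$chim_from) <= -delta,
      trigger = (.data$gm_trigger | .data$count_trigger) & .data$chimerism_falling
    )
  structure(
    list(subject_id = trajectory$subject_id,
         flag = any(evidence$trigger),
         evidence = evidence),
    class = "relapse_flag"
  )
}

#' @export
print.relapse_flag <- function(x, ...) {
  cat("<relapse_flag> subject", x$subject_id, "-",
      if (x$flag) "IMPENDING RELAPSE FLAGGED" else "no flag", "\n")
  print(x$evidence, ...)
  invisible(x)
}

#' @rdname flag_impending_relapse
#' @param x A `relapse_flag` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.relapse_flag <- function(x, ...) {
  x$evidence |> mutate(subject_id = x$subject_id, .before = 1)
}
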