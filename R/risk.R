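#' The adverse-risk myeloid gene set
#'
#' Returns the gene list used to separate adverse-risk ("high-risk
#' driver") somatic mutations from the rest of the panel, as defined by the
#' ELN, Pethema Registry and NCRI classifications for myeloid malignancies:
#' ASXL1, BCOR, EZH2, FLT3-ITD, RUNX1, SETBP1, SF3B1, SRSF2, STAG2, TP53,
#' U2AF1, ZRSR2 and WT1. FLT3-ITD is a distinct symbol - FLT3 point
#' mutations are not adverse-risk under this scheme. The set is shipped as
#' editable YAML so alternative risk schemes can be swapped in.
#'
#' @param path Optional path to a YAML file with fields `label` and
#'   `genes`; defaults to the packaged consensus list.
#' @return Character vector of gene symbols with a `label` attribute.
#' @export
adverse_risk_genes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "adverse_risk_genes.yaml",
                                package = "cfmrd", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  if (is.null(y$genes) || length(y$genes) == 0) {
    stop_cfmrd("risk gene set YAML must contain a non-empty 'genes' field",
               class = "cfmrd_schema_error")
  }
  genes <- toupper(as.character(y$genes))
  attr(genes, "label") <- y$label %||% basename(path)
  genes
}

#' Classify a gene symbol as adverse-risk or other
#'
#' Case-insensitive membership test against the risk set; internal tandem
#' duplication suffixes are respected, so `FLT3-ITD` is adverse while
#' `FLT3` is not.
#'
#' @param gene Character vector of gene symbols.
#' @param risk_set Character vector from [adverse_risk_genes()].
#' @return Character vector, `"adverse"` or `"other"`.
#' @examples
#' classify_gene(c("TP53", "DNMT3A", "FLT3-ITD", "FLT3"))
#' @export
classify_gene <- function(gene, risk_set = adverse_risk_genes()) {
  if_else(toupper(gene) %in% toupper(risk_set), "adverse", "other")
}

#' Classify a subject by adverse-risk mutation clearance
#'
#' Assigns each subject to one of the relapse-risk groups that organize
#' post-transplant cfDNA surveillance:
#'
#' * `not_evaluable` - no evaluable post-transplant plasma sample with
#'   gene-level data (for example death before the final sampling with the
#'   remaining samples not done);
#' * `no_adverse_ever` - no adverse-risk mutation at diagnosis or in any
#'   pre-transplant sample;
#' * `persistent_adverse` - at least one adverse-risk mutation in plasma at
#'   the last evaluable post-transplant timepoint;
#' * `mrd_negative_pre` - no somatic mutations at all in pre-transplant
#'   marrow or plasma (adverse-risk disease documented at diagnosis only);
#' * `cleared_pre` - adverse-risk mutations documented at diagnosis but
#'   absent from pre-transplant plasma;
#' * `cleared_post` - adverse-risk mutations in pre-transplant plasma,
#'   none at the last evaluable post-transplant plasma timepoint.
#'
#' Clearance "before transplantation" is judged on plasma cfDNA: a subject
#' whose pre-transplant marrow still carried an adverse-risk mutation that
#' plasma no longer detected counts as cleared_pre, consistent with a
#' plasma-centric surveillance protocol.
#'
#' @param trajectory An [build_trajectory()] object for the subject.
#' @param subject One-row subject tibble (needs `relapse_day`,
#'   `adverse_at_diagnosis`).
#' @param risk_set Character vector of adverse-risk genes.
#' @return One-row tibble: `subject_id`, `had_adverse_pre`, `group`,
#'   `relapsed_12mo`, `excluded_reason`.
#' @export
classify_subject <- function(trajectory, subject,
                             risk_set = adverse_risk_genes()) {
  sid <- trajectory$subject_id
  stopifnot(identical(subject$subject_id[[1]], sid))
  adverse_dx <- isTRUE(subject$adverse_at_diagnosis[[1]])
  relapsed <- !is.na(subject$relapse_day[[1]]) && subject$relapse_day[[1]] <= 365

  series <- trajectory$variant_series
  pre_rows <- series |> filter(.data$day == "pre", !is.na(.data$vaf))
  pre_plasma_adverse <- any(classify_gene(
    pre_rows$gene[pre_rows$compartment == "plasma"], risk_set) == "adverse")
  pre_any_adverse <- any(classify_gene(pre_rows$gene, risk_set) == "adverse")
  had_adverse_pre <- adverse_dx || pre_any_adverse

  row <- function(group, reason = NA_character_) {
    tibble(subject_id = sid, had_adverse_pre = had_adverse_pre,
           group = group, relapsed_12mo = relapsed, excluded_reason = reason)
  }

  last_day <- last_evaluable_plasma_day(trajectory)
  if (is.na(last_day)) {
    return(row("not_evaluable", "no evaluable post-transplant plasma sample"))
  }
  if (!had_adverse_pre) return(row("no_adverse_ever"))

  last_rows <- series |>
    filter(.data$day == last_day, .data$compartment == "plasma", !is.na(.data$vaf))
  if (any(classify_gene(last_rows$gene, risk_set) == "adverse")) {
    return(row("persistent_adverse"))
  }
  if (nrow(pre_rows) == 0) return(row("mrd_negative_pre"))
  if (!pre_plasma_adverse) return(row("cleared_pre"))
  row("cleared_post")
}

#' Classify every subject of a cohort
#'
#' Builds the residual-disease trajectory for each subject and applies
#' [classify_subject()].
#'
#' @param cohort A `cfdna_cohort` list (see [load_hsct_cohort()]) or any
#'   list with `subjects`, `variants` and optionally `sample_status`.
#' @param risk_set Character vector of adverse-risk genes.
#' @return Tibble with one row per subject.
#' @export
classify_cohort <- function(cohort, risk_set = adverse_risk_genes()) {
  purrr::map_dfr(cohort$subjects$subject_id, function(sid) {
    subj <- cohort$subjects |> filter(.data$subject_id == sid)
    traj <- build_trajectory(cohort$variants, subj,
                             sample_status = cohort$sample_status)
    classify_subject(traj, subj, risk_set)
  })
}

#' Relapse contingency by clearance group
#'
#' Summarizes subject risk classifications into per-group counts of
#' relapses within 12 months, plus the pooled two-by-two contingency of
#' persistent adverse-risk disease versus cleared-or-negative subjects
#' (among those with adverse-risk disease at baseline).
#'
#' @param classifications Tibble from [classify_cohort()] /
#'   [classify_subject()].
#' @return An object of class `relapse_summary`. [tidy()] returns the
#'   per-group table; [glance()] the pooled one-row summary; [autoplot()]
#'   a grouped-bar figure of subjects and relapses per group.
#' @export
summarize_relapse_by_group <- function(classifications) {
  if (nrow(classifications |> filter(.data$group != "not_evaluable")) < 1) {
    stop_not_evaluable("no evaluable classifications")
  }
  groups <- c("no_adverse_ever", "mrd_negative_pre", "cleared_pre",
              "cleared_post", "persistent_adverse", "not_evaluable")
  by_group <- classifications |>
    mutate(group = factor(.data$group, levels = groups)) |>
    group_by(.data$group, .drop = FALSE) |>
    summarise(n = dplyr::n(),
              relapses = sum(.data$relapsed_12mo),
              .groups = "drop") |>
    mutate(relapse_fraction = if_else(.data$n > 0, .data$relapses / .data$n, NA_real_))

  cleared_groups <- c("mrd_negative_pre", "cleared_pre", "cleared_post")
  pooled <- classifications |>
    filter(.data$had_adverse_pre,
           .data$group %in% c(cleared_groups, "persistent_adverse")) |>
    mutate(pooled = if_else(.data$group == "persistent_adverse",
                            "persistent_adverse", "cleared_or_negative")) |>
    group_by(.data$pooled) |>
    summarise(n = dplyr::n(), relapses = sum(.data$relapsed_12mo), .groups = "drop")

  structure(list(by_group = by_group, pooled = pooled), class = "relapse_summary")
}

#' @export
print.relapse_summary <- function(x, ...) {
  cat("<relapse_summary>\n")
  print(x$by_group, ...)
  cat("pooled (adverse-risk at baseline):\n")
  print(x$pooled, ...)
  invisible(x)
}

#' @rdname summarize_relapse_by_group
#' @param x A `relapse_summary` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.relapse_summary <- function(x, ...) x$by_group

#' @rdname summarize_relapse_by_group
#' @exportS3Method generics::glance
glance.relapse_summary <- function(x, ...) {
  get1 <- function(grp, col) {
    v <- x$pooled[[col]][x$pooled$pooled == grp]
    if (length(v) == 0) 0L else v
  }
  tibble(
    n_evaluable = sum(x$by_group$n[x$by_group$group != "not_evaluable"]),
    persistent_n = get1("persistent_adverse", "n"),
    persistent_relapses = get1("persistent_adverse", "relapses"),
    cleared_n = get1("cleared_or_negative", "n"),
    cleared_relapses = get1("cleared_or_negative", "relapses")
  )
}

#' @rdname summarize_relapse_by_group
#' @param object A `relapse_summary` object.
#' @exportS3Method ggplot2::autoplot
autoplot.relapse_summary <- function(object, ...) {
  d <- object$by_group |>
    tidyr::pivot_longer(c("n", "relapses"), names_to = "measure",
                        values_to = "count") |>
    mutate(measure = factor(.data$measure, levels = c("n", "relapses"),
                            labels = c("subjects", "relapses within 12 mo")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$count,
                                  fill = .data$measure)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "subjects",
                  title = "Relapse by adverse-risk mutation clearance group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
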