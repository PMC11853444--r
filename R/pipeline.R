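#' Run the full surveillance analysis on a cohort
#'
#' Orchestrates the standard pipeline: origin annotation and somatic
#' filtering (when the variant table arrives unannotated), per-sample
#' residual-disease aggregates, per-subject trajectories and clearance
#' classification, SNP-based donor chimerism, impending-relapse flags, and
#' the cohort statistics. Stages whose inputs are absent (for example no
#' SNP table) are skipped with a warning rather than failing the run.
#'
#' @param cohort A `cfdna_cohort` list ([load_hsct_cohort()],
#'   [simulate_cohort()]'s `$cohort`, or assembled from the readers).
#' @param risk_set Adverse-risk gene set.
#' @param germline_band_het,germline_band_hom VAF bands for
#'   [annotate_origin()] when origins are missing.
#' @param min_informative Minimum informative SNPs per chimerism estimate.
#' @param fold,count_rise,delta Impending-relapse thresholds
#'   (see [flag_impending_relapse()]).
#' @param seed Optional integer recorded in the manifest (the analysis
#'   itself is deterministic).
#' @return A list of class `cfmrd_run`: `mrd_samples`, `classifications`,
#'   `relapse_summary`, `chimerism`, `relapse_flags`, `stats`, `manifest`.
#' @export
run_analysis <- function(cohort, risk_set = adverse_risk_genes(),
                         germline_band_het = c(40, 60),
                         germline_band_hom = c(90, 100),
                         min_informative = 3,
                         fold = 3, count_rise = 3, delta = 2,
                         seed = NULL) {
  variants <- cohort$variants

  chimerism <- NULL
  if (!is.null(cohort$snp_observations) && nrow(cohort$snp_observations) > 0) {
    chimerism <- estimate_chimerism_by_sample(cohort$snp_observations,
                                              min_informative = min_informative)
  } else {
    rlang::warn("no SNP observations: chimerism stage skipped")
  }

  if (any(is.na(variants$origin))) {
    variants <- annotate_origin(variants,
                                germline_band_het = germline_band_het,
                                germline_band_hom = germline_band_hom,
                                chimerism = chimerism)
  }
  somatic <- filter_somatic(variants)

  classifications <- classify_cohort(
    list(subjects = cohort$subjects, variants = somatic,
         sample_status = cohort$sample_status),
    risk_set = risk_set
  )

  flags <- NULL
  if (!is.null(chimerism)) {
    flags <- purrr::map_dfr(cohort$subjects$subject_id, function(sid) {
      subj <- cohort$subjects |> filter(.data$subject_id == sid)
      traj <- build_trajectory(somatic, subj, cohort$sample_status)
      fl <- tryCatch(
        flag_impending_relapse(traj, chimerism, fold = fold,
                               count_rise = count_rise, delta = delta),
        cfmrd_not_evaluable = function(e) NULL
      )
      tibble(subject_id = sid,
             flagged = if (is.null(fl)) NA else fl$flag)
    })
  }

  pre <- somatic |> filter(.data$day == "pre")
  pre_counts <- cohort$subjects |>
    select("subject_id") |>
    tidyr::crossing(compartment = c("BM", "plasma")) |>
    left_join(pre |> count(.data$subject_id, .data$compartment),
              by = c("subject_id", "compartment")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  stats <- list(
    pre_count_kruskal = kruskal_wallis(pre_counts$n, pre_counts$compartment),
    pre_vaf_wilcoxon = tryCatch(
      wilcoxon_matched_pairs(build_paired_vafs(
        pre |> filter(.data$compartment == "BM"),
        pre |> filter(.data$compartment == "plasma")
      )),
      cfmrd_not_evaluable = function(e) NULL
    ),
    survival = survival_times(cohort$subjects)
  )

  structure(list(
    mrd_samples = mrd_summarize(somatic),
    classifications = classifications,
    relapse_summary = summarize_relapse_by_group(classifications),
    chimerism = chimerism,
    relapse_flags = flags,
    stats = stats,
    manifest = list(
      package_version = as.character(utils::packageVersion("cfmrd")),
      seed = seed,
      n_subjects = nrow(cohort$subjects),
      n_variant_calls = nrow(cohort$variants),
      risk_set_label = attr(risk_set, "label"),
      thresholds = list(fold = fold, count_rise = count_rise, delta = delta,
                        min_informative = min_informative,
                        germline_band_het = germline_band_het,
                        germline_band_hom = germline_band_hom)
    )
  ), class = "cfmrd_run")
}

#' @export
print.cfmrd_run <- function(x, ...) {
  cat("<cfmrd_run>", x$manifest$n_subjects, "subjects\n")
  print(x$relapse_summary, ...)
  invisible(x)
}

#' Write a run's report bundle to disk
#'
#' Emits the per-sample aggregates, classifications and chimerism as TSV,
#' the statistics and the manifest as JSON.
#'
#' @param run A `cfmrd_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(run$mrd_samples, file.path(dir, "mrd_samples.tsv"))
  readr::write_tsv(run$classifications, file.path(dir, "classifications.tsv"))
  if (!is.null(run$chimerism)) {
    readr::write_tsv(run$chimerism, file.path(dir, "chimerism.tsv"))
  }
  stats <- run$stats
  stats$survival <- NULL
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(run$stats$survival, file.path(dir, "survival.tsv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Recompute the packaged cohort's printed summary values
#'
#' Re-derives, from the per-gene variant calls shipped with the packaged
#' cohort, every benchmark the bundled summary tables print - per-sample
#' geometric means, day-84 concordance counts and median VAF, the
#' adverse-risk persistence/relapse contingency, the median relapse day,
#' and the count of subjects never MRD-positive after transplant - and
#' compares each computed value with its printed counterpart.
#'
#' @param tolerance Absolute tolerance for real-valued comparisons.
#' @return A tibble with `benchmark`, `computed`, `printed`, `pass`.
#' @export
reproduce_benchmarks <- function(tolerance = 0.05) {
  cohort <- load_hsct_cohort()
  gm_bench <- function(sid, day, comp) {
    vafs <- cohort$variants |>
      filter(.data$subject_id == sid, .data$day == !!day,
             .data$compartment == comp) |>
      pull(.data$vaf)
    geometric_mean_vaf(vafs)
  }
  printed_gm <- function(sid, day, comp) {
    cohort$mrd_cells |>
      filter(.data$subject_id == sid, .data$day == !!day,
             .data$compartment == comp) |>
      pull(.data$gm_vaf)
  }
  d84 <- cohort$variants |> filter(.data$day == "84")
  cls <- classify_cohort(cohort)
  rs <- glance(summarize_relapse_by_group(cls))

  plasma_counts <- cohort$mrd_cells |>
    filter(.data$compartment == "plasma", .data$day %in% c("28", "56", "84"),
           .data$status != "ND") |>
    group_by(.data$subject_id) |>
    summarise(all_negative = dplyr::n() == 3 && all(.data$n_mutations == 0),
              .groups = "drop")

  bench <- tibble(
    benchmark = c(
      "GM pre-transplant plasma, subject 002",
      "GM day-84 plasma, subject 010",
      "GM pre-transplant plasma, subject 019",
      "GM pre-transplant marrow, subject 019",
      "mutations in day-84 marrow",
      "mutations in day-84 plasma",
      "median day-84 plasma VAF (%)",
      "subjects with persistent adverse-risk mutations",
      "relapses among persistent-adverse subjects",
      "relapses among cleared/negative subjects",
      "median relapse day",
      "subjects MRD-negative at all three post-transplant plasma timepoints"
    ),
    computed = c(
      gm_bench("002", "pre", "plasma"),
      gm_bench("010", "84", "plasma"),
      gm_bench("019", "pre", "plasma"),
      gm_bench("019", "pre", "BM"),
      sum(d84$compartment == "BM"),
      sum(d84$compartment == "plasma"),
      median(d84$vaf[d84$compartment == "plasma"]),
      rs$persistent_n,
      rs$persistent_relapses,
      rs$cleared_relapses,
      median_range(cohort$subjects$relapse_day)$median,
      sum(plasma_counts$all_negative)
    ),
    printed = c(
      printed_gm("002", "pre", "plasma"),
      printed_gm("010", "84", "plasma"),
      printed_gm("019", "pre", "plasma"),
      printed_gm("019", "pre", "BM"),
      36, 36, 0.39, 9, 6, 0, 153, 1
    )
  )
  bench |> mutate(pass = abs(.data$computed - .data$printed) <= tolerance)
}
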