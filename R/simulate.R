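# Synthetic cohorts with the statistical structure the analysis assumes:
# Hardy-Weinberg donor/recipient SNP genotypes, a two-regime host-fraction
# trajectory (exponential engraftment clearance, exponential clonal
# regrowth for relapsing subjects), single-clone somatic VAF dynamics tied
# to the tumour-derived cfDNA fraction, and binomial read-count noise.

# non-adverse panel genes used to fill simulated mutation profiles
.other_panel_genes <- c(
  "DNMT3A", "TET2", "IDH1", "IDH2", "NRAS", "KRAS", "CBL", "PPM1D",
  "KMT2C", "KMT2D", "PDGFRB", "NOTCH1", "CHEK2", "GATA2", "CEBPA",
  "JAK2", "MPL", "CALR", "NF1", "BRAF"
)

#' Configure a synthetic cfDNA surveillance cohort
#'
#' All rates and sizes default to the study design the packaged cohort
#' follows: 20 subjects sampled at baseline and days 28/56/84, a 16-SNP
#' chimerism panel at allele frequency 0.5, sequencing depth 5,000, and a
#' roughly 30 percent relapse fraction. Host cfDNA clears with a 10-day
#' half-life toward a 5 percent engrafted floor; relapsing subjects seed a
#' regrowing clone (doubling time 14 days) from `relapse_onset_day`.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps SNPs on the chimerism panel.
#' @param snp_allele_freq Population alt-allele frequency for both donor
#'   and recipient genotypes (Hardy-Weinberg).
#' @param depth Sequencing depth (reads) per variant and per SNP.
#' @param timepoints Sampling days; day 0 is the pre-transplant baseline.
#' @param relapse_fraction Probability a subject is programmed to relapse.
#' @param clearance_halflife_days Half-life of the host cfDNA fraction.
#' @param regrowth_doubling_days Doubling time of the relapsing clone.
#' @param relapse_onset_day Day molecular regrowth begins.
#' @param relapse_seed_fraction Tumour cfDNA fraction of the regrowing
#'   clone at onset (0.04: a small but established molecular relapse).
#' @param relapse_burden_fraction Tumour cfDNA fraction at which clinical
#'   relapse is considered documented (defines the programmed relapse day).
#' @param adverse_gene_prob Probability each simulated mutation falls in
#'   an adverse-risk gene.
#' @param mutations_min,mutations_max Range of somatic mutations per
#'   subject (uniform).
#' @param baseline_vaf_min,baseline_vaf_max Baseline plasma VAF range
#'   (percent) from which clone sizes are back-calculated.
#' @param host_fraction_engrafted Residual host cfDNA fraction after full
#'   engraftment (non-haematopoietic tissue turnover).
#' @param plant_host_germline_prob,plant_donor_transmitted_prob
#'   Probability of planting one heterozygous host-germline variant /
#'   donor-transmitted variant per subject (for origin-annotation tests).
#' @param lod Limit of detection: observed VAFs (percent) below this are
#'   dropped from the emitted table.
#' @param seed Integer seed; required, all randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 20, n_snps = 16, snp_allele_freq = 0.5,
                       depth = 5000, timepoints = c(0, 28, 56, 84),
                       relapse_fraction = 0.3,
                       clearance_halflife_days = 10,
                       regrowth_doubling_days = 14,
                       relapse_onset_day = 40,
                       relapse_seed_fraction = 0.04,
                       relapse_burden_fraction = 0.5,
                       adverse_gene_prob = 0.6,
                       mutations_min = 1, mutations_max = 9,
                       baseline_vaf_min = 0.2, baseline_vaf_max = 50,
                       host_fraction_engrafted = 0.05,
                       plant_host_germline_prob = 0.2,
                       plant_donor_transmitted_prob = 0.1,
                       lod = 0.02, seed) {
  if (missing(seed)) stop_cfmrd("an explicit seed is required", "cfmrd_config_error")
  cfg <- as.list(environment())
  fracs <- c("snp_allele_freq", "relapse_fraction", "relapse_seed_fraction",
             "relapse_burden_fraction", "adverse_gene_prob",
             "host_fraction_engrafted", "plant_host_germline_prob",
             "plant_donor_transmitted_prob")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_cfmrd(paste0(f, " must lie in [0,1]"), "cfmrd_config_error")
    }
  }
  if (cfg$depth <= 0) stop_cfmrd("depth must be > 0", "cfmrd_config_error")
  if (is.unsorted(cfg$timepoints, strictly = TRUE)) {
    stop_cfmrd("timepoints must be strictly increasing", "cfmrd_config_error")
  }
  if (cfg$clearance_halflife_days <= 0 || cfg$regrowth_doubling_days <= 0) {
    stop_cfmrd("half-life and doubling time must be positive", "cfmrd_config_error")
  }
  if (cfg$mutations_min < 0 || cfg$mutations_max < cfg$mutations_min) {
    stop_cfmrd("invalid mutations_per_subject range", "cfmrd_config_error")
  }
  structure(cfg, class = "sim_config")
}

# tumour-derived cfDNA fraction at day t (before capping)
tumor_fraction <- function(t, cfg, relapse) {
  f <- (1 - cfg$host_fraction_engrafted) * 2^(-t / cfg$clearance_halflife_days)
  if (relapse) {
    f <- f + ifelse(
      t >= cfg$relapse_onset_day,
      cfg$relapse_seed_fraction *
        2^((t - cfg$relapse_onset_day) / cfg$regrowth_doubling_days),
      0
    )
  }
  pmin(f, 1 - cfg$host_fraction_engrafted)
}

host_fraction_at <- function(t, cfg, relapse) {
  pmin(cfg$host_fraction_engrafted + tumor_fraction(t, cfg, relapse), 1)
}

# Hardy-Weinberg genotype alt-fraction draw
draw_genotype <- function(n, p) {
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  sample(c(0, 0.5, 1), n, replace = TRUE, prob = probs)
}

#' Simulate one SNP chimerism panel measurement
#'
#' Draws donor and recipient genotypes under Hardy-Weinberg equilibrium
#' and a binomial read count per SNP at the expected mixture allele
#' fraction `v = h * g_R + (1 - h) * g_D`. Used by [simulate_cohort()] and
#' convenient for estimator calibration on its own.
#'
#' @param host_fraction True host (recipient) cfDNA fraction `h`.
#' @param n_snps Panel size.
#' @param allele_freq Population alt-allele frequency.
#' @param depth Reads per SNP.
#' @return A SNP observation tibble.
#' @export
simulate_snp_panel <- function(host_fraction, n_snps = 16, allele_freq = 0.5,
                               depth = 5000) {
  g_r <- draw_genotype(n_snps, allele_freq)
  g_d <- draw_genotype(n_snps, allele_freq)
  expected <- host_fraction * g_r + (1 - host_fraction) * g_d
  alt <- rbinom(n_snps, depth, expected)
  tibble(
    snp_id = sprintf("snp%02d", seq_len(n_snps)),
    recipient_gt = g_r, donor_gt = g_d,
    observed_vaf = alt / depth, depth = as.integer(depth)
  )
}

#' Simulate a post-transplant cfDNA surveillance cohort with ground truth
#'
#' Generates a full cohort dataset in the same shape the readers produce -
#' subjects, somatic variant calls (with origin left blank, as sequencing
#' output would arrive), SNP observations per timepoint - plus the ground
#' truth that produced it: true host fractions, expected VAF trajectories,
#' planted variant origins, and programmed relapse days. Deterministic
#' under a fixed seed; each subject draws from its own counter-derived
#' substream, so subject k's data do not change when `n_subjects` grows.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cfdna_sim`: list with `cohort` (subjects,
#'   variants, snp_observations, sample_status) and `truth` (subjects,
#'   host_fraction, variants, config).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_cfmrd("config must be created by sim_config()", "cfmrd_config_error")
  }
  cfg <- config
  risk <- adverse_risk_genes()
  day_lab <- function(t) ifelse(t == 0, "pre", as.character(t))

  per_subject <- purrr::map(seq_len(cfg$n_subjects), function(k) {
    # counter-derived substream, independent of n_subjects
    set.seed((cfg$seed %% 100000L) * 20011L + k * 7L)
    sid <- sprintf("S%03d", k)
    relapse <- runif(1) < cfg$relapse_fraction

    h_t <- host_fraction_at(cfg$timepoints, cfg, relapse)
    f_t <- tumor_fraction(cfg$timepoints, cfg, relapse)

    programmed_relapse <- NA_real_
    if (relapse) {
      programmed_relapse <- cfg$relapse_onset_day + cfg$regrowth_doubling_days *
        log2(cfg$relapse_burden_fraction / cfg$relapse_seed_fraction)
    }

    # somatic mutations: single clone, heterozygous, VAF = ccf * f(t) / 2
    n_mut <- sample(cfg$mutations_min:cfg$mutations_max, 1)
    is_adverse <- runif(n_mut) < cfg$adverse_gene_prob
    genes <- ifelse(is_adverse,
                    sample(risk, n_mut, replace = TRUE),
                    sample(.other_panel_genes, n_mut, replace = TRUE))
    vaf0 <- runif(n_mut, cfg$baseline_vaf_min, cfg$baseline_vaf_max)
    ccf <- pmin(1, (2 * vaf0 / 100) / f_t[1])
    somatic <- tidyr::crossing(
      tibble(gene = genes, idx = seq_len(n_mut), ccf = ccf, origin = "somatic"),
      tibble(t = cfg$timepoints)
    ) |>
      mutate(expected_vaf = 100 * .data$ccf *
               tumor_fraction(.data$t, cfg, relapse) / 2)

    planted <- list()
    if (runif(1) < cfg$plant_host_germline_prob) {
      g <- sample(.other_panel_genes, 1)
      planted$germ <- tibble(gene = g, idx = n_mut + 1L, ccf = NA_real_,
                             origin = "host_germline", t = cfg$timepoints,
                             expected_vaf = 50 * h_t)
    }
    if (runif(1) < cfg$plant_donor_transmitted_prob) {
      g <- sample(.other_panel_genes, 1)
      planted$donor <- tibble(gene = g, idx = n_mut + 2L, ccf = NA_real_,
                              origin = "donor_transmitted", t = cfg$timepoints,
                              expected_vaf = 50 * (1 - h_t))
    }
    truth_var <- bind_rows(c(list(somatic), unname(planted))) |>
      mutate(subject_id = sid,
             variant_key = paste0(.data$gene, "_m", .data$idx),
             day = day_lab(.data$t))

    observed <- truth_var |>
      mutate(
        alt = rbinom(dplyr::n(), cfg$depth, clamp01(.data$expected_vaf / 100)),
        vaf = 100 * .data$alt / cfg$depth
      ) |>
      filter(.data$vaf >= cfg$lod) |>
      mutate(compartment = "plasma", origin_out = NA_character_) |>
      select("subject_id", "day", compartment = "compartment",
             "gene", "variant_key", "vaf", origin = "origin_out")

    # SNP chimerism panel: genotypes fixed per subject, one binomial read
    # draw per timepoint
    g_r <- draw_genotype(cfg$n_snps, cfg$snp_allele_freq)
    g_d <- draw_genotype(cfg$n_snps, cfg$snp_allele_freq)
    snps <- tidyr::crossing(tibble(snp = seq_len(cfg$n_snps)),
                            tibble(t = cfg$timepoints)) |>
      mutate(
        h = host_fraction_at(.data$t, cfg, relapse),
        expected = .data$h * g_r[.data$snp] + (1 - .data$h) * g_d[.data$snp],
        alt = rbinom(dplyr::n(), cfg$depth, .data$expected),
        subject_id = sid, day = day_lab(.data$t),
        snp_id = sprintf("snp%02d", .data$snp),
        recipient_gt = g_r[.data$snp], donor_gt = g_d[.data$snp],
        observed_vaf = .data$alt / cfg$depth, depth = as.integer(cfg$depth)
      ) |>
      select("subject_id", "day", "snp_id", "recipient_gt", "donor_gt",
             "observed_vaf", "depth")

    subject_row <- tibble(
      subject_id = sid, diagnosis = "simulated myeloid malignancy",
      relapse_day = if (relapse && programmed_relapse <= 365)
        as.integer(round(programmed_relapse)) else NA_integer_,
      death_day = NA_integer_, last_followup_day = 365L,
      consolidation_start_day = NA_integer_,
      adverse_at_diagnosis = any(is_adverse)
    )
    truth_subject <- tibble(subject_id = sid, relapse = relapse,
                            programmed_relapse_day = programmed_relapse)
    truth_h <- tibble(subject_id = sid, day = day_lab(cfg$timepoints),
                      t = cfg$timepoints, host_fraction = h_t,
                      donor_percent = 100 * (1 - h_t))

    list(subject = subject_row, variants = observed, snps = snps,
         truth_subject = truth_subject, truth_h = truth_h,
         truth_var = truth_var |>
           select("subject_id", "day", "gene", "variant_key", "origin",
                  "ccf", "expected_vaf"))
  })

  pull_bind <- function(field) bind_rows(purrr::map(per_subject, field))
  subjects <- pull_bind("subject")
  variants <- as_variant_tbl(pull_bind("variants"))
  sample_status <- variants |>
    distinct(.data$subject_id, .data$day, .data$compartment) |>
    tidyr::complete(subject_id = subjects$subject_id,
                    day = day_lab(cfg$timepoints),
                    compartment = "plasma") |>
    mutate(status = "tested", gene_level = TRUE)

  structure(
    list(
      cohort = structure(list(
        subjects = subjects,
        variants = variants,
        snp_observations = pull_bind("snps"),
        sample_status = sample_status,
        mrd_cells = NULL, discrepancies = NULL
      ), class = "cfdna_cohort"),
      truth = list(
        subjects = pull_bind("truth_subject"),
        host_fraction = pull_bind("truth_h"),
        variants = pull_bind("truth_var"),
        config = cfg
      )
    ),
    class = "cfdna_sim"
  )
}

#' @export
print.cfdna_sim <- function(x, ...) {
  cat("<cfdna_sim>", nrow(x$cohort$subjects), "subjects,",
      sum(x$truth$subjects$relapse), "programmed relapses\n")
  invisible(x)
}

#' Score analysis outputs against simulation ground truth
#'
#' Runs the standard analyses on a simulated cohort (or accepts
#' already-computed outputs) and reports recovery metrics:
#'
#' * `chimerism`: mean/max absolute error of estimated donor chimerism
#'   against `100 * (1 - h)`;
#' * `clearance`: confusion matrix of per-subject adverse-risk persistence
#'   calls against the truth (a subject truly persists when any adverse
#'   mutation's expected VAF at the last timepoint is at or above the
#'   detection limit);
#' * `relapse_flag`: sensitivity of the impending-relapse flag among
#'   programmed relapses, specificity among non-relapses, and the mean
#'   lead time from flag day to programmed relapse day.
#'
#' @param sim A `cfdna_sim` object from [simulate_cohort()].
#' @param chimerism Optional precomputed chimerism estimates
#'   (from [estimate_chimerism_by_sample()]).
#' @return A list of tibbles: `chimerism`, `clearance`, `relapse_flag`.
#' @export
recovery_report <- function(sim, chimerism = NULL) {
  if (!inherits(sim, "cfdna_sim")) {
    stop_cfmrd("sim must come from simulate_cohort()", "cfmrd_key_error")
  }
  cohort <- sim$cohort
  truth <- sim$truth
  cfg <- truth$config

  chim <- chimerism %||% estimate_chimerism_by_sample(cohort$snp_observations)
  if (any(is.na(cohort$variants$origin))) {
    cohort$variants <- suppressWarnings(
      annotate_origin(cohort$variants, chimerism = chim)
    )
  }
  cohort$variants <- filter_somatic(cohort$variants)
  chim_scored <- chim |>
    inner_join(truth$host_fraction |>
                 select("subject_id", "day", true_donor = "donor_percent"),
               by = c("subject_id", "day"))
  if (nrow(chim_scored) < nrow(chim)) {
    stop_cfmrd("chimerism estimates carry identifiers absent from the truth",
               "cfmrd_key_error")
  }
  chim_tbl <- chim_scored |>
    summarise(mae = mean(abs(.data$donor_percent - .data$true_donor)),
              max_abs_error = max(abs(.data$donor_percent - .data$true_donor)),
              n = dplyr::n())

  # truth persistence: any adverse-risk mutation still expected at/above
  # the LOD at the last sampled timepoint
  last_day <- ifelse(max(cfg$timepoints) == 0, "pre", as.character(max(cfg$timepoints)))
  risk <- adverse_risk_genes()
  truth_persist <- truth$variants |>
    filter(.data$origin == "somatic", .data$day == last_day,
           classify_gene(.data$gene, risk) == "adverse") |>
    group_by(.data$subject_id) |>
    summarise(true_persistent = any(.data$expected_vaf >= cfg$lod), .groups = "drop")

  cls <- classify_cohort(cohort)
  clearance <- cls |>
    left_join(truth_persist, by = "subject_id") |>
    mutate(true_persistent = dplyr::coalesce(.data$true_persistent, FALSE),
           called_persistent = .data$group == "persistent_adverse") |>
    filter(.data$group != "not_evaluable") |>
    count(.data$true_persistent, .data$called_persistent)

  flags <- purrr::map_dfr(cohort$subjects$subject_id, function(sid) {
    subj <- cohort$subjects |> filter(.data$subject_id == sid)
    traj <- build_trajectory(cohort$variants, subj, cohort$sample_status)
    fl <- tryCatch(flag_impending_relapse(traj, chim),
                   cfmrd_not_evaluable = function(e) NULL)
    post <- traj$samples |>
      filter(.data$compartment == "plasma", .data$day != "pre")
    detectable <- any(post$n_mutations > 0, na.rm = TRUE)
    if (is.null(fl)) {
      return(tibble(subject_id = sid, flagged = NA, flag_day = NA_real_,
                    mrd_detectable = detectable))
    }
    day <- if (fl$flag) min(day_key(fl$evidence$day_to[fl$evidence$trigger])) else NA_real_
    tibble(subject_id = sid, flagged = fl$flag, flag_day = day,
           mrd_detectable = detectable)
  }) |>
    left_join(truth$subjects, by = "subject_id")
  relapse_tbl <- flags |>
    summarise(
      sensitivity = mean(.data$flagged[.data$relapse], na.rm = TRUE),
      # an MRD-based flag is undefined for relapses the panel never sees:
      # score detectable relapses separately
      sensitivity_detectable = mean(
        .data$flagged[.data$relapse & .data$mrd_detectable], na.rm = TRUE),
      specificity = mean(!.data$flagged[!.data$relapse], na.rm = TRUE),
      mean_lead_days = mean(
        (.data$programmed_relapse_day - .data$flag_day)[.data$relapse],
        na.rm = TRUE
      ),
      flags_before_relapse = sum(
        .data$flagged & .data$flag_day <= .data$programmed_relapse_day &
          .data$relapse, na.rm = TRUE
      ),
      n_relapse = sum(.data$relapse)
    )

  list(chimerism = chim_tbl, clearance = clearance, relapse_flag = relapse_tbl)
}
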