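test_that("geometric mean reproduces tabulated per-sample summaries", {
  expect_equal(geometric_mean_vaf(c(63.57, 28.71)), 42.72)
  expect_equal(geometric_mean_vaf(c(17.76, 15.04, 19.57, 12.98, 12.92, 0.8)), 9.43)
  expect_equal(geometric_mean_vaf(5.0), 5.0)
  expect_true(is.na(geometric_mean_vaf(numeric(0))))
  expect_error(geometric_mean_vaf(c(5, 0)), class = "cfmrd_value_error")
})

test_that("GM is scale-equivariant, permutation-invariant and bounded by the range", {
  set.seed(81)
  for (rep in 1:20) {
    v <- runif(sample(1:10, 1), 0.01, 60)
    g <- geometric_mean_vaf(v, digits = NULL)
    expect_gte(g, min(v))
    expect_lte(g, max(v))
    expect_equal(geometric_mean_vaf(v[sample.int(length(v))], digits = NULL), g)
    c_ <- runif(1, 0.1, 1.5)
    expect_equal(geometric_mean_vaf(c_ * v, digits = NULL), c_ * g,
                 tolerance = 1e-10)
  }
})

cohort <- load_hsct_cohort()

test_that("trajectories keep ND, NE and zero-count states distinct", {
  # subject 008: every tested sample is mutation-free (NE), none are ND
  t008 <- build_trajectory(cohort$variants, "008", cohort$sample_status,
                           extra_cells = cohort$mrd_cells)
  expect_true(all(t008$samples$status == "NE"))
  expect_true(all(t008$samples$n_mutations == 0))

  # subject 001: day-84 samples were not done; distinct from zero-count
  t001 <- build_trajectory(cohort$variants, "001", cohort$sample_status)
  s <- t001$samples
  expect_equal(s$status[s$day == "84"], c("ND", "ND"))
  expect_true(all(is.na(s$n_mutations[s$day == "84"])))
  expect_equal(s$status[s$day == "pre" & s$compartment == "BM"], "ok")

  # empty call list but tested gene-level slots -> all zero-count
  full_status <- tidyr::crossing(
    subject_id = "008", day = c("pre", "28", "56", "84"), compartment = "plasma"
  ) |> dplyr::mutate(status = "tested", gene_level = TRUE)
  t_empty <- build_trajectory(cohort$variants[0, ], "008", full_status)
  expect_true(all(t_empty$samples$n_mutations == 0))

  expect_error(build_trajectory(cohort$variants, cohort$subjects[0, ]),
               class = "cfmrd_key_error")
})

test_that("clearance status follows the last evaluable plasma sample", {
  risk <- adverse_risk_genes()

  # subject 020: adverse ASXL1 pre, only DNMT3A left at day 84
  t020 <- build_trajectory(cohort$variants, "020", cohort$sample_status)
  c020 <- detect_clearance(t020)
  expect_equal(c020$status[c020$gene == "ASXL1"], "cleared_post")
  expect_equal(c020$first_cleared_day[c020$gene == "ASXL1"], "84")
  expect_equal(c020$status[c020$gene == "DNMT3A"], "persistent")

  # subject 002: TP53 present pre and at day 84
  t002 <- build_trajectory(cohort$variants, "002", cohort$sample_status)
  c002 <- detect_clearance(t002)
  expect_equal(c002$status[c002$gene == "TP53"], "persistent")

  # last evaluable wins: present pre, absent day 28, back at day 84
  calls <- make_calls("sX", c("pre", "84"), "plasma", c("TP53", "TP53"),
                      c(40, 2))
  status <- tibble::tibble(subject_id = "sX", day = c("pre", "28", "84"),
                           compartment = "plasma", status = "tested",
                           gene_level = TRUE)
  tX <- build_trajectory(calls, "sX", status)
  expect_equal(detect_clearance(tX)$status, "persistent")

  # ND final sample must not count as clearance (no evaluable post sample)
  t001 <- build_trajectory(cohort$variants, "001", cohort$sample_status)
  expect_error(detect_clearance(t001), class = "cfmrd_not_evaluable")

  # statuses partition the observed genes
  c_all <- detect_clearance(t020, genes = "all")
  expect_setequal(c_all$gene, unique(t020$variant_series$gene))
  expect_true(all(c_all$status %in%
                    c("never_present", "cleared_pre", "cleared_post", "persistent")))

  # diagnosis-only gene -> cleared_pre
  cdx <- detect_clearance(t020, genes = "EZH2", diagnosis_genes = "EZH2")
  expect_equal(cdx$status, "cleared_pre")
})

test_that("impending-relapse flag needs a burden rise plus falling chimerism", {
  # the published early-relapse pattern: GM 0.64 -> 19.28 -> 33.48
  t010 <- build_trajectory(cohort$variants, "010", cohort$sample_status,
                           extra_cells = cohort$mrd_cells)
  falling <- tibble::tibble(subject_id = "010", day = c("28", "56", "84"),
                            donor_percent = c(90, 70, 40))
  fl <- flag_impending_relapse(t010, falling)
  expect_true(fl$flag)
  ev <- tidy(fl)
  expect_true(any(ev$gm_trigger & ev$chimerism_falling))

  # flat burden and stable chimerism -> no flag
  calls <- make_calls("sF", c("28", "56", "84"), "plasma",
                      c("TP53", "TP53", "TP53"), c(0.5, 0.5, 0.5))
  stable <- tibble::tibble(subject_id = "sF", day = c("28", "56", "84"),
                           donor_percent = c(95, 95, 95))
  tF <- build_trajectory(calls, "sF")
  expect_false(flag_impending_relapse(tF, stable)$flag)

  # rising burden without chimerism fall -> no flag
  calls2 <- make_calls("sR", c("28", "56"), "plasma", c("TP53", "TP53"),
                       c(0.5, 5))
  tR <- build_trajectory(calls2, "sR")
  up <- tibble::tibble(subject_id = "sR", day = c("28", "56"),
                       donor_percent = c(95, 96))
  expect_false(flag_impending_relapse(tR, up)$flag)

  expect_error(
    flag_impending_relapse(build_trajectory(calls2[1, ], "sR"), up),
    class = "cfmrd_not_evaluable"
  )
})

test_that("flag precedes the programmed relapse day for most detectable simulated relapses", {
  sim <- simulate_cohort(sim_config(n_subjects = 100, relapse_fraction = 1,
                                    depth = 5000, seed = 7))
  rr <- recovery_report(sim)
  expect_gte(rr$relapse_flag$sensitivity_detectable, 0.8)
  expect_gt(rr$relapse_flag$mean_lead_days, 0)
})
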