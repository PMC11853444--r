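test_that("informative SNP selection keeps differing genotypes with pair classes", {
  obs <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    recipient_gt = c(1, 0.5, 0, 1),
    donor_gt = c(0, 0.5, 0.5, 0.5),
    observed_vaf = 0.5, depth = 100L
  )
  info <- select_informative(obs)
  expect_setequal(info$snp_id, c("a", "c", "d"))
  expect_equal(info$pair_class[info$snp_id == "a"], "hom_hom")
  expect_equal(info$pair_class[info$snp_id == "c"], "hom_het")
})

test_that("expected informative count matches Hardy-Weinberg enumeration at p = 0.5", {
  # exact enumeration of genotype-pair probabilities: every unequal pair of
  # alt-fractions in {0, 0.5, 1} differs by at least 0.5, so
  # P(informative) = 1 - sum(p_i^2) = 0.625 and a 16-SNP panel carries
  # 10 informative SNPs on average
  p <- 0.5
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  gts <- c(0, 0.5, 1)
  p_diff <- sum(outer(probs, probs) * (abs(outer(gts, gts, "-")) >= 0.5))
  expect_equal(16 * p_diff, 10)

  # the simulator's genotype draws agree in the long run
  set.seed(11)
  n_inf <- replicate(400, nrow(select_informative(simulate_snp_panel(0.5, 16, 0.5, 10))))
  expect_lt(abs(mean(n_inf) - 10), 0.5)
})

test_that("estimator is exact on noise-free mixtures for any h and genotype mix", {
  pairs <- informative_pairs()
  set.seed(21)
  for (h in c(0, runif(20), 1)) {
    idx <- sample(nrow(pairs), 8, replace = TRUE)
    panel <- exact_snp_panel(h, pairs$g_r[idx], pairs$g_d[idx])
    fit <- estimate_donor_chimerism(panel, digits = 3)
    expect_equal(fit$donor_percent, round(100 * (1 - h), 3), tolerance = 1e-6)
  }
  # pure donor: v = g_D everywhere
  panel <- exact_snp_panel(0, c(1, 1, 0), c(0, 0.5, 1))
  expect_equal(estimate_donor_chimerism(panel)$donor_percent, 100)
  # single-class linear mixture closed form
  panel <- tibble::tibble(snp_id = letters[1:4], recipient_gt = 1, donor_gt = 0,
                          observed_vaf = 0.25, depth = 1000L)
  expect_equal(estimate_donor_chimerism(panel)$donor_percent, 75)
})

test_that("median estimator agrees with the least-squares grid oracle on noise-free input", {
  pairs <- informative_pairs()
  set.seed(31)
  for (rep in 1:25) {
    h <- runif(1)
    n <- sample(3:8, 1)
    idx <- sample(nrow(pairs), n, replace = TRUE)
    panel <- exact_snp_panel(h, pairs$g_r[idx], pairs$g_d[idx])
    fit <- estimate_donor_chimerism(panel)
    h_grid <- grid_host_fraction(panel)
    expect_lte(abs(fit$host_fraction - h_grid), 0.001)
  }
})

test_that("output is clamped to [0,100] under out-of-range noise", {
  panel <- tibble::tibble(
    snp_id = letters[1:4], recipient_gt = c(1, 1, 0, 0), donor_gt = c(0, 0, 1, 1),
    observed_vaf = c(1, 1, 0, 0), depth = 100L # pure recipient, beyond h = 1
  )
  expect_equal(estimate_donor_chimerism(panel)$donor_percent, 0)
  panel$observed_vaf <- c(0, 0, 1, 1)
  expect_equal(estimate_donor_chimerism(panel)$donor_percent, 100)
})

test_that("shifting observations toward the recipient genotype lowers donor percent", {
  pairs <- informative_pairs()
  set.seed(41)
  for (rep in 1:10) {
    h <- runif(1, 0.1, 0.8)
    idx <- sample(nrow(pairs), 6, replace = TRUE)
    panel <- exact_snp_panel(h, pairs$g_r[idx], pairs$g_d[idx])
    shifted <- panel
    step <- 0.05 * sign(panel$recipient_gt - panel$donor_gt)
    shifted$observed_vaf <- pmin(pmax(panel$observed_vaf + step, 0), 1)
    expect_lte(estimate_donor_chimerism(shifted, digits = 4)$donor_percent,
               estimate_donor_chimerism(panel, digits = 4)$donor_percent)
  }
})

test_that("too few informative SNPs or zero coverage is not evaluable", {
  panel <- tibble::tibble(snp_id = c("a", "b"), recipient_gt = c(1, 0.5),
                          donor_gt = c(0, 0.5), observed_vaf = 0.2, depth = 100L)
  expect_error(estimate_donor_chimerism(panel), class = "cfmrd_not_evaluable")
  panel <- tibble::tibble(snp_id = letters[1:3], recipient_gt = 1, donor_gt = 0,
                          observed_vaf = 0, depth = 0L)
  expect_error(estimate_donor_chimerism(panel), class = "cfmrd_not_evaluable")
})

test_that("binomial-noise recovery: simulated h = 0.20 lands within 2 points of 80", {
  set.seed(51)
  panel <- simulate_snp_panel(0.20, n_snps = 8, allele_freq = 0.5, depth = 10000)
  fit <- estimate_donor_chimerism(panel)
  expect_lt(abs(fit$donor_percent - 80), 2)
})

test_that("mean absolute error stays under 2 points across 200 mixtures at depth 5000", {
  set.seed(61)
  err <- replicate(200, {
    h <- runif(1, 0.05, 0.95)
    panel <- simulate_snp_panel(h, n_snps = 16, allele_freq = 0.5, depth = 5000)
    fit <- tryCatch(estimate_donor_chimerism(panel),
                    cfmrd_not_evaluable = function(e) NULL)
    if (is.null(fit)) NA_real_ else abs(fit$donor_percent - 100 * (1 - h))
  })
  expect_lte(mean(err, na.rm = TRUE), 2)
})

test_that("depth weighting changes nothing on equal depths and is available", {
  panel <- tibble::tibble(snp_id = letters[1:5], recipient_gt = 1, donor_gt = 0,
                          observed_vaf = c(0.1, 0.12, 0.15, 0.2, 0.22),
                          depth = 1000L)
  expect_equal(estimate_donor_chimerism(panel, weight_by_depth = TRUE)$donor_percent,
               estimate_donor_chimerism(panel)$donor_percent)
})

test_that("chimerism trend classification follows the delta rule", {
  expect_equal(chimerism_trend(c(95.5, 90, 84)), "falling")
  expect_equal(chimerism_trend(c(88, 88, 88)), "stable")
  expect_equal(chimerism_trend(c(60, 40, 12)), "falling")
  expect_equal(chimerism_trend(c(80, 85, 92)), "rising")
  expect_equal(chimerism_trend(c(80, 85, 84)), "stable")
  expect_error(chimerism_trend(85), class = "cfmrd_not_evaluable")
})

test_that("method comparison reports Pearson r per nominal day", {
  a <- tidyr::crossing(subject_id = sprintf("s%d", 1:5), day = c(28, 56)) |>
    dplyr::mutate(donor_percent = 50 + 5 * seq_len(10))
  b <- a |> dplyr::mutate(donor_percent = 100 - donor_percent / 2)
  cc <- compare_chimerism_methods(a, a)
  expect_true(all(tidy(cc)$r == 1))
  cc2 <- compare_chimerism_methods(a, b)
  expect_true(all(tidy(cc2)$r == -1))

  # off-schedule days align to the nominal grid
  b_shift <- b |> dplyr::mutate(day = day + c(10, -9))
  expect_equal(tidy(compare_chimerism_methods(a, b_shift))$r, c(-1, -1))

  # independent series: |r| small on average under the null
  set.seed(71)
  rs <- replicate(40, {
    x <- tidyr::crossing(subject_id = sprintf("s%d", 1:20), day = 28) |>
      dplyr::mutate(donor_percent = runif(20, 50, 100))
    y <- x |> dplyr::mutate(donor_percent = runif(20, 50, 100))
    tidy(compare_chimerism_methods(x, y))$r
  })
  expect_lt(abs(mean(rs)), 0.15)
  expect_error(compare_chimerism_methods(a[1:2, ], b[1:2, ]),
               class = "cfmrd_not_evaluable")
})

test_that("SNP tables read from TSV and minimal VCF agree", {
  skip_if_not_installed("vcfR")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\trecipient_gt\tdonor_gt\tobserved_vaf\tdepth",
    "rs1\t1/1\t0/0\t0.30\t500",
    "rs2\t0/1\t0/0\t0.15\t400",
    "rs3\t0/0\t0/0\t0.01\t450"
  ), tsv)
  x <- read_snp_tsv(tsv)
  expect_equal(x$recipient_gt, c(1, 0.5, 0))
  expect_equal(x$donor_gt, c(0, 0, 0))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tRCP\tDNR\tPLS",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:AD\t1/1:0,10\t0/0:12,0\t0/1:350,150",
    "chr2\t200\trs2\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:5,5\t0/0:9,0\t0/0:340,60"
  ), vcf)
  y <- read_snp_vcf(vcf, recipient = "RCP", donor = "DNR", plasma = "PLS")
  expect_equal(y$recipient_gt, c(1, 0.5))
  expect_equal(y$observed_vaf, c(150 / 500, 60 / 400))
  expect_equal(y$depth, c(500L, 400L))
  expect_error(read_snp_vcf(vcf, "nope", "DNR", "PLS"), class = "cfmrd_key_error")
})
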