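test_that("paired VAF records cover the union of keys with zeros for missing sides", {
  bm <- make_calls("002", "pre", "BM", c("TP53", "HNF1A"), c(48.34, 24.54))
  pl <- make_calls("002", "pre", "plasma", c("TP53", "HNF1A"), c(63.57, 28.71))
  pairs <- build_paired_vafs(bm, pl)
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$vaf_bm > 0 & pairs$vaf_plasma > 0))

  bm2 <- make_calls("003", "pre", "BM", c("BCOR", "KMT2D"), c(13.85, 8.8))
  pairs2 <- build_paired_vafs(bm2, pl[0, ])
  expect_equal(nrow(pairs2), 2)
  expect_true(all(pairs2$vaf_plasma == 0))

  expect_equal(nrow(build_paired_vafs(bm[0, ], pl[0, ])), 0)

  # swapping compartments transposes the pair values
  swapped <- build_paired_vafs(
    dplyr::mutate(pl, compartment = "BM"),
    dplyr::mutate(bm, compartment = "plasma")
  )
  expect_equal(swapped$vaf_bm, pairs$vaf_plasma)
  expect_equal(swapped$vaf_plasma, pairs$vaf_bm)

  dup <- dplyr::bind_rows(bm, bm) |> dplyr::mutate(variant_key = gene)
  expect_error(build_paired_vafs(dup, pl), class = "cfmrd_value_error")
})

test_that("signed-rank exact p matches full sign enumeration for n <= 10", {
  set.seed(101)
  for (n in c(5, 7, 10)) {
    for (rep in 1:10) {
      d <- round(runif(n, -10, 10), 2)
      d <- d[d != 0]
      # avoid ties in |d| so the exact path is taken
      while (any(duplicated(abs(d))) || length(d) < n) {
        d <- round(runif(n, -10, 10), 2); d <- d[d != 0]
      }
      pairs <- tibble::tibble(vaf_bm = 0, vaf_plasma = d)
      res <- wilcoxon_matched_pairs(pairs)
      oracle <- wilcoxon_enum(d)
      expect_equal(res$statistic, oracle$statistic)
      expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
      expect_equal(res$method, "exact")
    }
  }
})

test_that("signed-rank handles zeros, direction and symmetry", {
  # doubling series: all differences positive
  pairs <- tibble::tibble(vaf_bm = 1:5, vaf_plasma = 2 * (1:5))
  res <- wilcoxon_matched_pairs(pairs)
  oracle <- wilcoxon_enum(pairs$vaf_plasma - pairs$vaf_bm)
  expect_equal(res$statistic, 15) # all ranks positive
  expect_equal(res$p_value, oracle$p)

  # all zero differences -> not evaluable
  same <- tibble::tibble(vaf_bm = 1:6, vaf_plasma = 1:6)
  expect_error(wilcoxon_matched_pairs(same), class = "cfmrd_not_evaluable")

  # zero-difference pairs are dropped, not counted
  with_zeros <- dplyr::bind_rows(pairs, same)
  res2 <- wilcoxon_matched_pairs(with_zeros)
  expect_equal(res2$n_used, 5)
  expect_equal(res2$p_value, res$p_value)

  # swapping columns keeps the p-value (two-sided symmetry)
  res_swap <- wilcoxon_matched_pairs(
    tibble::tibble(vaf_bm = pairs$vaf_plasma, vaf_plasma = pairs$vaf_bm)
  )
  expect_equal(res_swap$p_value, res$p_value)
})

test_that("Kruskal-Wallis matches the rank-formula oracle and base R", {
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  res <- kruskal_wallis(list(g1, g2))
  vals <- c(g1, g2); grp <- rep(1:2, each = 3)
  expect_equal(res$statistic, kw_oracle(vals, grp))
  expect_equal(res$df, 1)

  set.seed(111)
  vals <- c(rnorm(8), rnorm(10, 1), sample(1:4, 6, replace = TRUE))
  grp <- rep(1:3, c(8, 10, 6))
  res2 <- kruskal_wallis(vals, grp)
  expect_equal(res2$statistic, kw_oracle(vals, grp), tolerance = 1e-12)

  # identical values across groups -> H = 0, p = 1
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p_value, 1)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(121)
  vals <- rexp(30); grp <- rep(1:3, each = 10)
  h0 <- kruskal_wallis(vals, grp)$statistic
  for (f in list(function(x) x^3, exp, function(x) 5 * x + 2, log1p)) {
    expect_equal(kruskal_wallis(f(vals), grp)$statistic, h0, tolerance = 1e-12)
  }
})

test_that("median_range summarizes like the cohort reports", {
  expect_equal(median_range(c(170, 62, 168, 52, 167, 139))[1:3],
               tibble::tibble(median = 153, min = 52, max = 170))
  expect_equal(median_range(7)$median, 7)
  expect_equal(median_range(c(1, 2, 3, 4))$median, 2.5)
  set.seed(131)
  v <- runif(9)
  expect_equal(median_range(sample(v)), median_range(v))
  expect_error(median_range(numeric(0)), class = "cfmrd_not_evaluable")
})

test_that("survival times follow the day-0 definitions with censoring", {
  subjects <- tibble::tibble(
    subject_id = c("010", "x", "001"),
    relapse_day = c(52L, NA, NA),
    death_day = c(125L, NA, 59L),
    last_followup_day = c(125L, 365L, 59L)
  )
  st <- survival_times(subjects)
  expect_equal(st$rfs_days, c(52, 365, 59))
  expect_equal(st$os_days, c(125, 365, 59))
  expect_equal(st$event_rfs, c(TRUE, FALSE, TRUE))
  expect_equal(st$event_os, c(TRUE, FALSE, TRUE))
  expect_true(all(st$rfs_days <= st$os_days))

  bad <- tibble::tibble(subject_id = "z", relapse_day = 200L,
                        death_day = 100L, last_followup_day = 100L)
  expect_error(survival_times(bad), class = "cfmrd_value_error")
})
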