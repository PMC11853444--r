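# Independent oracles and small fixture builders used across tests.

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments
# (mid-ranks on absolute differences). Independent of stats::wilcox.test.
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(statistic = v_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Kruskal-Wallis H from the rank-sum formula with tie correction.
kw_oracle <- function(values, group) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, group, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Brute-force least-squares grid search for the host fraction.
grid_host_fraction <- function(snps, step = 0.001) {
  grid <- seq(0, 1, by = step)
  sse <- vapply(grid, function(h) {
    sum((snps$observed_vaf -
           (h * snps$recipient_gt + (1 - h) * snps$donor_gt))^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Noise-free SNP panel at an exact mixture fraction.
exact_snp_panel <- function(h, g_r, g_d, depth = 10000L) {
  tibble::tibble(
    snp_id = sprintf("s%02d", seq_along(g_r)),
    recipient_gt = g_r, donor_gt = g_d,
    observed_vaf = h * g_r + (1 - h) * g_d,
    depth = depth
  )
}

# Minimal variant tibble builder.
make_calls <- function(subject, day, compartment, gene, vaf,
                       origin = "somatic", variant_key = NULL) {
  tb <- tibble::tibble(subject_id = subject, day = day,
                       compartment = compartment, gene = gene, vaf = vaf,
                       origin = origin)
  if (!is.null(variant_key)) tb$variant_key <- variant_key
  as_variant_tbl(tb)
}

# Informative genotype pairs (g_R != g_D) for random draws.
informative_pairs <- function() {
  pairs <- expand.grid(g_r = c(0, 0.5, 1), g_d = c(0, 0.5, 1))
  pairs[abs(pairs$g_r - pairs$g_d) >= 0.5, ]
}
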