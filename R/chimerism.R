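#' Read a SNP observation table
#'
#' Tab-separated table of chimerism-informative SNP measurements from one
#' plasma sample: `snp_id`, `recipient_gt` and `donor_gt` as diploid
#' genotypes (`0/0`, `0/1`, `1/1`) or as expected alt-allele fractions
#' (0, 0.5, 1), `observed_vaf` (fraction in \[0,1\]) and `depth` (reads).
#' May also carry `subject_id` and `day` columns for multi-sample tables.
#'
#' @param path Path to a TSV file.
#' @return A tibble of SNP observations with numeric genotype fractions.
#' @export
read_snp_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    recipient_gt = readr::col_character(),
    donor_gt = readr::col_character(),
    observed_vaf = readr::col_double(),
    depth = readr::col_integer(),
    .default = readr::col_character()
  ))
  x$recipient_gt <- gt_fraction(x$recipient_gt)
  x$donor_gt <- gt_fraction(x$donor_gt)
  validate_snp_tbl(as_tibble(x))
}

gt_fraction <- function(gt) {
  gt <- as.character(gt)
  out <- dplyr::case_match(
    gt,
    c("0/0", "0|0", "0") ~ 0,
    c("0/1", "1/0", "0|1", "1|0", "0.5") ~ 0.5,
    c("1/1", "1|1", "1") ~ 1,
    .default = NA_real_
  )
  if (any(is.na(out) & !is.na(gt))) {
    stop_cfmrd(paste0("unrecognized genotype token(s): ",
                      paste(unique(gt[is.na(out) & !is.na(gt)]), collapse = ", ")),
               class = "cfmrd_value_error")
  }
  out
}

validate_snp_tbl <- function(x) {
  required <- c("snp_id", "recipient_gt", "donor_gt", "observed_vaf", "depth")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_cfmrd(paste0("SNP table is missing column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "cfmrd_schema_error")
  }
  ok <- x$recipient_gt %in% c(0, 0.5, 1) & x$donor_gt %in% c(0, 0.5, 1) &
    x$observed_vaf >= 0 & x$observed_vaf <= 1 & x$depth >= 0
  if (any(!ok)) {
    stop_cfmrd(paste0("SNP observation row(s) failed validation: ",
                      paste(which(!ok), collapse = ", ")),
               class = "cfmrd_value_error")
  }
  x
}

#' Read SNP genotypes and plasma allele depths from a minimal VCF
#'
#' Reads a VCF v4.2 subset carrying three samples: the recipient and donor
#' genotype columns (`GT`) and a plasma cfDNA sample with allelic depths
#' (`AD`, `ref,alt`). Positions are 1-based as per VCF. Multi-allelic
#' records are not supported.
#'
#' @param path Path to an uncompressed VCF file.
#' @param recipient,donor,plasma Sample names in the VCF.
#' @return A SNP observation tibble as from [read_snp_tsv()].
#' @export
read_snp_vcf <- function(path, recipient, donor, plasma) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_cfmrd("reading VCF input requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  for (s in c(recipient, donor, plasma)) {
    if (!s %in% colnames(gt)) {
      stop_cfmrd(paste0("sample not found in VCF: ", s), class = "cfmrd_key_error")
    }
  }
  fix <- vcfR::getFIX(vcf)
  ad_counts <- do.call(rbind, lapply(strsplit(ad[, plasma], ","), as.integer))
  depth <- ad_counts[, 1] + ad_counts[, 2]
  tibble(
    snp_id = unname(paste0(fix[, "CHROM"], ":", fix[, "POS"], ":",
                           fix[, "REF"], ">", fix[, "ALT"])),
    recipient_gt = unname(gt_fraction(gt[, recipient])),
    donor_gt = unname(gt_fraction(gt[, donor])),
    observed_vaf = unname(ifelse(depth > 0, ad_counts[, 2] / depth, NA_real_)),
    depth = as.integer(unname(depth))
  ) |> validate_snp_tbl()
}

#' Select chimerism-informative SNPs
#'
#' A SNP is informative for the donor/recipient mixture when the two
#' genotypes differ (their expected alt-allele fractions differ by at least
#' 0.5). Each kept observation is annotated with its genotype-pair class:
#' `hom_hom` (opposite homozygotes, full-signal) or `hom_het` (homozygote
#' vs heterozygote, half-signal).
#'
#' @param observations A SNP observation tibble.
#' @return The informative subset with a `pair_class` column.
#' @export
select_informative <- function(observations) {
  observations |>
    filter(abs(.data$recipient_gt - .data$donor_gt) >= 0.5) |>
    mutate(pair_class = if_else(
      .data$recipient_gt %in% c(0, 1) & .data$donor_gt %in% c(0, 1),
      "hom_hom", "hom_het"
    ))
}

#' Estimate donor chimerism from plasma SNP allele fractions
#'
#' Under the linear mixture model the observed alt fraction at an
#' informative SNP is `v = h * g_R + (1 - h) * g_D`, where `h` is the host
#' (recipient) fraction of the cfDNA and `g_R`, `g_D` the genotype
#' alt-allele fractions. Each informative SNP therefore yields a host
#' fraction estimate `h_i = (v_i - g_D) / (g_R - g_D)`, clamped to
#' \[0, 1\] so a single noisy SNP cannot contribute an out-of-range value,
#' and the sample estimate is the median of the `h_i` (mean of the two
#' central values for an even count). Donor chimerism is
#' `100 * (1 - median(h_i))` percent. For opposite-homozygote SNPs this
#' reduces to the median VAF difference from the donor genotype; SNPs where
#' only one party is heterozygous are rescaled by 2 by the same formula.
#'
#' An optional depth-weighted median is available for panels with very
#' uneven coverage; the default estimator weights all informative SNPs
#' equally.
#'
#' @param observations A SNP observation tibble for one sample.
#' @param min_informative Minimum number of informative SNPs; below this
#'   the sample is not evaluable (error of class `cfmrd_not_evaluable`).
#' @param weight_by_depth Use a depth-weighted median of the per-SNP
#'   estimates.
#' @param digits Decimal places for the reported `donor_percent`.
#' @return An object of class `chimerism_fit` with fields `donor_percent`
#'   (rounded), `host_fraction` (unrounded), `n_informative`, `method`, and
#'   the per-SNP table. [tidy()] returns the per-SNP table; [glance()]
#'   returns the one-row summary.
#' @examples
#' panel <- tibble::tibble(
#'   snp_id = paste0("rs", 1:4), recipient_gt = 1, donor_gt = 0,
#'   observed_vaf = 0.25, depth = 1000L
#' )
#' glance(estimate_donor_chimerism(panel))
#' @export
estimate_donor_chimerism <- function(observations, min_informative = 3,
                                     weight_by_depth = FALSE, digits = 1) {
  observations <- validate_snp_tbl(observations)
  info <- select_informative(observations)
  if (nrow(info) < min_informative) {
    stop_not_evaluable(paste0("only ", nrow(info), " informative SNP(s); ",
                              min_informative, " required"))
  }
  if (all(info$depth == 0)) {
    stop_not_evaluable("zero depth on all informative SNPs")
  }
  info <- info |>
    mutate(host_hat = clamp01(
      (.data$observed_vaf - .data$donor_gt) / (.data$recipient_gt - .data$donor_gt)
    ))
  h <- if (weight_by_depth) {
    weighted_median(info$host_hat, info$depth)
  } else {
    stats::median(info$host_hat)
  }
  structure(
    list(
      donor_percent = round_half_up(100 * (1 - h), digits),
      host_fraction = h,
      n_informative = nrow(info),
      method = if (weight_by_depth) "cfDNA_NGS_depth_weighted" else "cfDNA_NGS",
      snps = info
    ),
    class = "chimerism_fit"
  )
}

# lower weighted median: smallest x with cumulative weight >= half;
# averages the two central values when the split is exact (matches the
# unweighted median on equal weights).
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' @export
print.chimerism_fit <- function(x, ...) {
  cat("<chimerism_fit> donor", paste0(x$donor_percent, "%"),
      "from", x$n_informative, "informative SNPs (", x$method, ")\n")
  invisible(x)
}

#' @rdname estimate_donor_chimerism
#' @param x A `chimerism_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chimerism_fit <- function(x, ...) as_tibble(x$snps)

#' @rdname estimate_donor_chimerism
#' @exportS3Method generics::glance
glance.chimerism_fit <- function(x, ...) {
  tibble(donor_percent = x$donor_percent, host_fraction = x$host_fraction,
         n_informative = x$n_informative, method = x$method)
}

#' Estimate donor chimerism for every sample in a SNP table
#'
#' Groups a multi-sample SNP observation table by `subject_id` and `day`
#' and applies [estimate_donor_chimerism()] to each group. Samples that are
#' not evaluable (too few informative SNPs, no coverage) are returned with
#' `donor_percent = NA` rather than failing the whole table.
#'
#' @inheritParams estimate_donor_chimerism
#' @return Tibble with one row per sample: `subject_id`, `day`, `method`,
#'   `donor_percent`, `n_informative`.
#' @export
estimate_chimerism_by_sample <- function(observations, min_informative = 3,
                                         weight_by_depth = FALSE, digits = 1) {
  observations |>
    group_by(.data$subject_id, .data$day) |>
    dplyr::group_modify(function(g, key) {
      fit <- tryCatch(
        estimate_donor_chimerism(g, min_informative, weight_by_depth, digits),
        cfmrd_not_evaluable = function(e) NULL
      )
      if (is.null(fit)) {
        tibble(method = "cfDNA_NGS", donor_percent = NA_real_,
               n_informative = NA_integer_)
      } else {
        tibble(method = fit$method, donor_percent = fit$donor_percent,
               n_informative = fit$n_informative)
      }
    }) |>
    ungroup()
}

#' Classify the trend of a chimerism series
#'
#' `falling` when every successive difference is at most `-delta`
#' percentage points, `rising` when every difference is at least `+delta`,
#' otherwise `stable`. Relapsing patients typically show a constant
#' downward cfDNA chimerism trend while lineage-sorted cellular chimerism
#' can remain uninformative.
#'
#' @param donor_percent Time-ordered numeric vector (at least 2 values).
#' @param delta Trend threshold in percentage points.
#' @return `"falling"`, `"rising"` or `"stable"`.
#' @examples
#' chimerism_trend(c(95.5, 90, 84))
#' @export
chimerism_trend <- function(donor_percent, delta = 2) {
  donor_percent <- donor_percent[!is.na(donor_percent)]
  if (length(donor_percent) < 2) {
    stop_not_evaluable("need at least 2 chimerism estimates for a trend")
  }
  d <- diff(donor_percent)
  if (all(d <= -delta)) "falling" else if (all(d >= delta)) "rising" else "stable"
}

#' Correlate two chimerism methods at matched timepoints
#'
#' Joins two estimate series on (subject, nominal day) - actual sampling
#' days are aligned to the study schedule with [nominal_day()] - and
#' reports the Pearson correlation per nominal day.
#'
#' @param a,b Tibbles with `subject_id`, `day`, `donor_percent`.
#' @param min_pairs Minimum matched pairs per day (default 3).
#' @return An object of class `chimerism_cor`; [tidy()] returns one row
#'   per nominal day with `r`, `n`, `p_value`.
#' @export
compare_chimerism_methods <- function(a, b, min_pairs = 3) {
  norm <- function(x, suffix) {
    out <- x |>
      mutate(nominal = as.character(nominal_day(suppressWarnings(as.integer(.data$day))))) |>
      select("subject_id", "nominal", "donor_percent")
    names(out)[names(out) == "donor_percent"] <- paste0("donor_", suffix)
    out
  }
  pairs <- inner_join(norm(a, "a"), norm(b, "b"), by = c("subject_id", "nominal")) |>
    filter(!is.na(.data$donor_a), !is.na(.data$donor_b))
  if (nrow(pairs) < min_pairs) {
    stop_not_evaluable(paste0("fewer than ", min_pairs, " matched pairs"))
  }
  by_day <- pairs |>
    group_by(day = .data$nominal) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < min_pairs) {
        return(tibble(r = NA_real_, n = nrow(g), p_value = NA_real_))
      }
      ct <- stats::cor.test(g$donor_a, g$donor_b, method = "pearson")
      tibble(r = unname(ct$estimate), n = nrow(g), p_value = ct$p.value)
    }) |>
    ungroup()
  structure(list(by_day = by_day, pairs = pairs), class = "chimerism_cor")
}

#' @export
print.chimerism_cor <- function(x, ...) {
  cat("<chimerism_cor> Pearson correlation by nominal day\n")
  print(x$by_day, ...)
  invisible(x)
}

#' @rdname compare_chimerism_methods
#' @param x A `chimerism_cor` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chimerism_cor <- function(x, ...) x$by_day
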