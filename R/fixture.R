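#' Load the packaged 20-subject transplant surveillance cohort
#'
#' Returns the bundled pilot cohort of twenty adults transplanted for
#' myeloid malignancies with plasma cfDNA panel sequencing at baseline and
#' days 28/56/84, shipped with the package so every analysis runs without
#' external data. The dataset carries:
#'
#' * `subjects` - clinical course (diagnosis, relapse/death days,
#'   consolidation, whether adverse-risk mutations were documented at
#'   diagnosis or pre-transplant work-up),
#' * `variants` - per-gene somatic VAFs at the pre-transplant and day-84
#'   timepoints in bone marrow and plasma (germline and donor-transmitted
#'   calls were excluded at source),
#' * `mrd_cells` - the printed per-sample mutation-count / geometric-mean
#'   summary at all six sample slots (gene-level detail exists only at the
#'   pre and day-84 timepoints; day 28/56 cells are summary-only),
#' * `sample_status` - which sample slots were tested vs not done (`ND`),
#' * `discrepancies` - cells where the two source tables disagree as
#'   printed. Both versions are retained verbatim rather than reconciled;
#'   integrity checks exclude the flagged cells.
#' * `demographics` - cohort-level demographic metadata.
#'
#' The VAF column of the shipped variant table contains two typographic
#' slash-decimal tokens exactly as printed; the reader normalizes them with
#' a warning (suppressed here).
#'
#' @return A list of tibbles with class `cfdna_cohort`.
#' @examples
#' cohort <- load_hsct_cohort()
#' dplyr::count(cohort$variants, day, compartment)
#' @export
load_hsct_cohort <- function() {
  path <- function(f) system.file("extdata", f, package = "cfmrd", mustWork = TRUE)
  variants <- suppressWarnings(read_variant_tsv(path("hsct20_variants.tsv")))
  subjects <- read_subject_sheet(path("hsct20_subjects.csv"))
  mrd_cells <- readr::read_tsv(path("hsct20_mrd_cells.tsv"), col_types = readr::cols(
    subject_id = readr::col_character(), day = readr::col_character(),
    compartment = readr::col_character(), n_mutations = readr::col_integer(),
    gm_vaf = readr::col_double(), status = readr::col_character()
  ))
  discrepancies <- readr::read_tsv(path("hsct20_discrepancies.tsv"),
                                   col_types = readr::cols(.default = readr::col_character()))
  demographics <- readr::read_tsv(path("hsct20_demographics.tsv"),
                                  col_types = readr::cols(.default = readr::col_character()))
  sample_status <- mrd_cells |>
    mutate(status = if_else(.data$status == "ND", "ND", "tested"),
           # gene-level per-variant data exists at pre and day-84 slots only
           gene_level = .data$day %in% c("pre", "84")) |>
    select("subject_id", "day", "compartment", "status", "gene_level")
  structure(
    list(
      subjects = subjects,
      variants = variants,
      mrd_cells = mrd_cells,
      sample_status = sample_status,
      snp_observations = tibble(
        subject_id = character(), day = character(), snp_id = character(),
        recipient_gt = numeric(), donor_gt = numeric(),
        observed_vaf = numeric(), depth = integer()
      ),
      discrepancies = discrepancies,
      demographics = demographics
    ),
    class = "cfdna_cohort"
  )
}

#' @export
print.cfdna_cohort <- function(x, ...) {
  cat("<cfdna_cohort>\n")
  cat("  subjects:          ", nrow(x$subjects), "\n")
  cat("  variant calls:     ", nrow(x$variants), "\n")
  cat("  summary cells:     ", nrow(x$mrd_cells), "\n")
  cat("  SNP observations:  ", nrow(x$snp_observations), "\n")
  if (!is.null(x$discrepancies) && nrow(x$discrepancies) > 0) {
    cat("  flagged table discrepancies:", nrow(x$discrepancies), "\n")
  }
  invisible(x)
}
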