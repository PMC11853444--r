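#' Read a somatic variant table
#'
#' Reads a tab-separated variant table with one row per variant observation.
#' Required columns: `subject_id`, `day` (`"pre"` or a non-negative integer),
#' `compartment` (`BM` or `plasma`), `gene`, and `vaf` (percent). Optional
#' columns `variant_key` (defaults to the gene symbol, suffixed for repeated
#' mutations in one gene) and `origin` (`somatic`, `host_germline`,
#' `donor_germline`, `donor_transmitted`; defaults to `NA`).
#'
#' VAF tokens that carry a typographic slash in the decimal position (such
#' as `0/73`) are normalized to decimal points with a warning; this artefact
#' occurs in published tables where decimal points were typeset as slashes.
#' Rows failing validation are rejected with their row numbers.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of validated variant calls.
#' @seealso [filter_somatic()], [annotate_origin()], [write_variant_tsv()]
#' @export
read_variant_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  as_variant_tbl(raw)
}

#' Validate and type a variant table
#'
#' Workhorse behind [read_variant_tsv()]; accepts any data frame with the
#' required columns (useful when variant calls arrive from another tool's
#' output already in memory).
#'
#' @param x A data frame with at least `subject_id`, `day`, `compartment`,
#'   `gene` and `vaf` columns.
#' @return A tibble with typed, validated columns `subject_id`, `day`,
#'   `compartment`, `gene`, `variant_key`, `vaf`, `origin`.
#' @export
as_variant_tbl <- function(x) {
  required <- c("subject_id", "day", "compartment", "gene", "vaf")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_cfmrd(
      paste0("variant table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "cfmrd_schema_error"
    )
  }
  x <- as_tibble(x)
  if (!"variant_key" %in% names(x)) x$variant_key <- NA_character_
  if (!"origin" %in% names(x)) x$origin <- NA_character_

  vaf_chr <- as.character(x$vaf)
  slashed <- grepl("^[0-9]+/[0-9]+$", vaf_chr)
  if (any(slashed)) {
    rlang::warn(paste0(
      "normalized ", sum(slashed),
      " VAF token(s) with a typographic slash to decimal points (rows ",
      paste(which(slashed), collapse = ", "), ")"
    ))
    vaf_chr[slashed] <- sub("/", ".", vaf_chr[slashed], fixed = TRUE)
  }
  vaf <- suppressWarnings(as.numeric(vaf_chr))

  day <- as.character(x$day)
  day_ok <- day == "pre" | grepl("^[0-9]+$", day)
  comp_ok <- x$compartment %in% c("BM", "plasma")
  vaf_ok <- !is.na(vaf) & vaf >= 0 & vaf <= 100
  origin_ok <- is.na(x$origin) |
    x$origin %in% c("somatic", "host_germline", "donor_germline", "donor_transmitted")

  bad <- which(!(day_ok & comp_ok & vaf_ok & origin_ok))
  if (length(bad) > 0) {
    stop_cfmrd(
      paste0("variant table row(s) failed validation: ",
             paste(bad, collapse = ", "),
             " (day must be 'pre' or an integer >= 0; compartment BM|plasma; ",
             "VAF within [0,100]; origin one of the known classes)"),
      class = "cfmrd_value_error"
    )
  }

  out <- tibble(
    subject_id = as.character(x$subject_id),
    day = day,
    compartment = as.character(x$compartment),
    gene = as.character(x$gene),
    variant_key = as.character(x$variant_key),
    vaf = vaf,
    origin = as.character(x$origin)
  )
  # Default keys: gene symbol, disambiguated by descending VAF for repeated
  # mutations in the same gene so the k-th largest clone keeps one key across
  # compartments and timepoints.
  out <- out |>
    group_by(.data$subject_id, .data$day, .data$compartment, .data$gene) |>
    mutate(
      .rank = rank(-.data$vaf, ties.method = "first"),
      .multi = dplyr::n() > 1,
      variant_key = if_else(
        is.na(.data$variant_key),
        if_else(.data$.multi, paste0(.data$gene, "_", .data$.rank), .data$gene),
        .data$variant_key
      )
    ) |>
    ungroup() |>
    select(-".rank", -".multi")

  dup <- out |>
    count(.data$subject_id, .data$day, .data$compartment, .data$gene,
          .data$variant_key) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_cfmrd(
      paste0("duplicate variant keys within a sample: ",
             paste(paste(dup$subject_id, dup$day, dup$compartment, dup$gene,
                         dup$variant_key, sep = ":"), collapse = "; ")),
      class = "cfmrd_value_error"
    )
  }
  out
}

#' Write a variant table to TSV
#'
#' @param calls A variant tibble as returned by [read_variant_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Read a subject sheet
#'
#' Comma-separated clinical course sheet with one row per subject:
#' `subject_id`, `diagnosis`, `relapse_day`, `death_day`,
#' `last_followup_day`, `consolidation_start_day`, plus optional columns
#' such as `adverse_at_diagnosis` (logical; whether adverse-risk mutations
#' were documented at diagnosis or in pre-transplant work-up).
#'
#' @param path Path to a CSV file.
#' @return A tibble of subject records.
#' @export
read_subject_sheet <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_guess()
  ))
  required <- c("subject_id", "diagnosis", "relapse_day", "death_day",
                "last_followup_day", "consolidation_start_day")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_cfmrd(paste0("subject sheet is missing column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "cfmrd_schema_error")
  }
  bad <- !is.na(x$death_day) & x$death_day > x$last_followup_day
  if (any(bad)) {
    stop_cfmrd(paste0("death_day after last_followup_day for subject(s): ",
                      paste(x$subject_id[bad], collapse = ", ")),
               class = "cfmrd_value_error")
  }
  as_tibble(x)
}

#' Keep somatic variant calls only
#'
#' Drops presumed germline mutations of host origin and any attributed to
#' donor transmission (donor germline either present in the graft or
#' engrafting clonal haematopoiesis), which would otherwise contaminate
#' residual-disease summaries. Calls must carry `origin` annotations, either
#' from the input table or from [annotate_origin()]. Order is preserved and
#' the operation is idempotent.
#'
#' @param calls A variant tibble with an `origin` column.
#' @return The somatic subset of `calls`.
#' @export
filter_somatic <- function(calls) {
  if (any(is.na(calls$origin))) {
    stop_cfmrd("calls carry missing origin annotations; run annotate_origin() first",
               class = "cfmrd_value_error")
  }
  calls[calls$origin == "somatic", , drop = FALSE]
}

#' Annotate the likely origin of each variant call
#'
#' The published exclusion of host-germline and donor-transmitted variants
#' states an outcome, not a detection rule; this function implements a
#' configurable heuristic for datasets that arrive unannotated:
#'
#' * **host_germline** - the pre-transplant VAF lies in the heterozygous
#'   band (default \[40, 60\]) or homozygous band (default \[90, 100\]) in
#'   every pre-transplant compartment in which the variant was observed.
#'   Subjects without any pre-transplant sample skip this rule (warning).
#' * **donor_transmitted** - absent pre-transplant, present at every
#'   post-transplant timepoint, and at each timepoint the VAF lies within
#'   `donor_tol` points of half the concurrent donor cfDNA fraction (a
#'   heterozygous donor variant tracking engraftment). Requires `chimerism`
#'   estimates; without them the rule is skipped.
#' * everything else - **somatic**.
#'
#' Calls whose `origin` is already known are left untouched.
#'
#' @param calls A variant tibble.
#' @param germline_band_het,germline_band_hom Length-2 numeric VAF bands
#'   (percent) for heterozygous and homozygous host germline variants.
#' @param chimerism Optional tibble with `subject_id`, `day`,
#'   `donor_percent` (as from [estimate_chimerism_by_sample()]).
#' @param donor_tol Tolerance (VAF points) around half the donor fraction.
#' @return `calls` with `origin` filled in.
#' @export
annotate_origin <- function(calls,
                            germline_band_het = c(40, 60),
                            germline_band_hom = c(90, 100),
                            chimerism = NULL,
                            donor_tol = 10) {
  calls <- as_variant_tbl(calls)
  key_cols <- c("subject_id", "gene", "variant_key")

  pre <- calls |> filter(.data$day == "pre")
  post <- calls |> filter(.data$day != "pre")
  post_days <- post |> distinct(.data$subject_id, .data$day)

  no_pre <- setdiff(unique(calls$subject_id), unique(pre$subject_id))
  if (length(no_pre) > 0) {
    rlang::warn(paste0(
      "no pre-transplant sample for subject(s) ",
      paste(no_pre, collapse = ", "),
      "; host-germline detection skipped for them"
    ))
  }

  in_band <- function(v) {
    (v >= germline_band_het[1] & v <= germline_band_het[2]) |
      (v >= germline_band_hom[1] & v <= germline_band_hom[2])
  }
  germ <- pre |>
    group_by(across(dplyr::all_of(key_cols))) |>
    summarise(host_germline = all(in_band(.data$vaf)), .groups = "drop")

  donor <- NULL
  if (!is.null(chimerism) && nrow(post) > 0) {
    chim <- chimerism |>
      mutate(day = as.character(.data$day)) |>
      select("subject_id", "day", "donor_percent")
    n_days <- post_days |> count(.data$subject_id, name = "n_days")
    donor <- post |>
      mutate(day = as.character(.data$day)) |>
      left_join(chim, by = c("subject_id", "day")) |>
      group_by(across(dplyr::all_of(key_cols))) |>
      summarise(
        at_all = dplyr::n_distinct(.data$day),
        tracks_donor = all(!is.na(.data$donor_percent) &
                             abs(.data$vaf - .data$donor_percent / 2) <= donor_tol),
        .groups = "drop"
      ) |>
      left_join(n_days, by = "subject_id") |>
      mutate(donor_transmitted = .data$tracks_donor & .data$at_all == .data$n_days) |>
      select(dplyr::all_of(key_cols), "donor_transmitted")
  }

  seen_pre <- pre |> distinct(across(dplyr::all_of(key_cols))) |> mutate(.pre = TRUE)
  out <- calls |>
    left_join(germ, by = key_cols) |>
    left_join(seen_pre, by = key_cols)
  if (!is.null(donor)) {
    out <- out |> left_join(donor, by = key_cols)
  } else {
    out$donor_transmitted <- FALSE
  }
  out |>
    mutate(
      origin = case_when(
        !is.na(.data$origin) ~ .data$origin,
        isTRUE_v(.data$host_germline) ~ "host_germline",
        !isTRUE_v(.data$.pre) & isTRUE_v(.data$donor_transmitted) ~ "donor_transmitted",
        TRUE ~ "somatic"
      )
    ) |>
    select(-"host_germline", -".pre", -"donor_transmitted")
}

# vectorized isTRUE with NA -> FALSE
isTRUE_v <- function(x) !is.na(x) & x
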