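#' Plot per-variant VAF trajectories
#'
#' One panel per subject, log-scaled VAF over time; the pre-transplant
#' timepoint is drawn at day -14 for spacing. Useful for eyeballing
#' clearance versus regrowth patterns across a cohort.
#'
#' @param variants Somatic variant tibble (plasma rows are plotted).
#' @param subjects Optional subject ids to include.
#' @return A ggplot object.
#' @export
plot_vaf_trajectories <- function(variants, subjects = NULL) {
  d <- variants |> filter(.data$compartment == "plasma")
  if (!is.null(subjects)) d <- d |> filter(.data$subject_id %in% subjects)
  d <- d |> mutate(t = if_else(.data$day == "pre", -14, day_key(.data$day)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$vaf,
                                  group = paste(.data$gene, .data$variant_key),
                                  colour = .data$gene)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "day after transplant (pre shown at -14)",
                  y = "VAF (%) in plasma cfDNA", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot donor chimerism series
#'
#' @param estimates Tibble with `subject_id`, `day`, `donor_percent`
#'   (and optionally `method`).
#' @param highlight Optional subject ids drawn in colour (e.g. relapses).
#' @return A ggplot object.
#' @export
plot_chimerism_series <- function(estimates, highlight = NULL) {
  d <- estimates |>
    filter(.data$day != "pre") |>
    mutate(t = day_key(.data$day),
           highlighted = .data$subject_id %in% (highlight %||% character(0)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$donor_percent,
                                  group = .data$subject_id,
                                  colour = .data$highlighted)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "day after transplant", y = "donor chimerism (%)") +
    ggplot2::theme_minimal()
}
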