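#' Plot absorbance traces with their fitted zero-order kinetics
#'
#' Faceted by sample and enzyme, one colour per replicate; QC-rejected
#' traces are drawn dashed.
#'
#' @param readings Raw readings tibble.
#' @param fits Matching [fit_activities()] output.
#' @return A ggplot object.
#' @export
plot_traces <- function(readings, fits = fit_activities(readings)) {
  d <- dplyr::left_join(
    readings,
    dplyr::select(fits, "sample_id", "fraction", "enzyme_class",
                  "replicate", "slope", "intercept", "qc_pass"),
    by = c("sample_id", "fraction", "enzyme_class", "replicate")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$absorbance,
                                  colour = factor(.data$replicate))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(
      data = dplyr::distinct(d, .data$sample_id, .data$enzyme_class,
                             .data$replicate, .data$slope, .data$intercept,
                             .data$qc_pass),
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = factor(.data$replicate),
                   linetype = .data$qc_pass)
    ) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   name = "QC pass") +
    ggplot2::facet_grid(sample_id ~ enzyme_class) +
    ggplot2::labs(x = "time (h)", y = "absorbance (AU)",
                  colour = "replicate")
}

#' Stacked share of reactor-level activity per source
#'
#' @param breakdown Output of [activity_shares()].
#' @return A ggplot object.
#' @export
plot_activity_shares <- function(breakdown) {
  ggplot2::ggplot(breakdown,
                  ggplot2::aes(.data$enzyme_class, .data$share_pct,
                               fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of reactor-level activity (%)",
                  fill = "source")
}

#' @method autoplot hydrolysis_capacity
#' @export
autoplot.hydrolysis_capacity <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$enzyme_class, .data$capacity_mg_cod_l,
                               fill = .data$biomolecule)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "capacity (mg COD per L influent)",
                  fill = "biomolecule")
}

#' @method autoplot reactor_activity
#' @export
autoplot.reactor_activity <- function(object, ...) {
  plot_activity_shares(activity_shares(object))
}
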