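#' Dot plot of CTC and tdEV counts per cohort
#'
#' Jittered dot plot of the two counts per cohort on a log10(count + 1)
#' scale with median bars — the standard way to show that tdEV counts
#' run roughly an order of magnitude above CTC counts in every cohort.
#'
#' @param data A tibble with columns `cohort`, `ctc_count`, `tdev_count`.
#' @return A ggplot object.
#' @export
plot_count_summary <- function(data) {
  check_columns(data, c("cohort", "ctc_count", "tdev_count"),
                what = "cohort table")
  long <- data |>
    tidyr::pivot_longer(c("ctc_count", "tdev_count"),
                        names_to = "marker", values_to = "count") |>
    dplyr::mutate(marker = sub("_count$", "", .data$marker))
  meds <- long |>
    dplyr::group_by(.data$cohort, .data$marker) |>
    dplyr::summarise(count = median(.data$count), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker,
                                     y = .data$count + 1,
                                     colour = .data$marker)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::geom_crossbar(
      data = meds,
      ggplot2::aes(ymin = .data$count + 1, ymax = .data$count + 1),
      width = 0.5, colour = "black", linewidth = 0.3
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~cohort, nrow = 1) +
    ggplot2::scale_colour_manual(
      values = c(ctc = "grey20", tdev = "grey55"), guide = "none"
    ) +
    ggplot2::labs(x = NULL, y = "Count + 1 per 7.5 mL") +
    ggplot2::theme_minimal()
}
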