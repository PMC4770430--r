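#' Plot DMR-centered mean methylation profiles
#'
#' @param profile A `dmr_profile` tibble from [dmr_mean_profile()].
#' @return A ggplot: one line per sample group over the window offsets.
#' @export
plot_dmr_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset, y = .data$mean_rpm,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "offset from DMR midpoint (bp)",
                  y = "mean rpm", colour = "group") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dmr_profile <- function(object, ...) plot_dmr_profile(object)

#' Plot gene counts per collaborative methylation pattern
#'
#' @param counts A `cdmp_counts` tibble from [summarize_pattern_counts()].
#' @param controls Controls to display (default: all except unions).
#' @return A ggplot bar chart, one panel per control, bars per tumor group.
#' @export
plot_pattern_counts <- function(counts, controls = NULL) {
  df <- dplyr::filter(counts, .data$tumor != "ANY")
  if (!is.null(controls)) {
    df <- dplyr::filter(df, .data$control %in% controls)
  }
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$label, y = .data$n_genes,
                               fill = .data$tumor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$control), ncol = 1) +
    ggplot2::labs(x = "pattern", y = "genes with DMRs", fill = "tumor group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cdmp_counts <- function(object, ...) plot_pattern_counts(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
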