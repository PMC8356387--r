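#' Violin plots of per-droplet QC metrics
#'
#' Total UMIs, detected genes, and mitochondrial (and, when present, mouse)
#' UMI percentage per droplet, split by filter outcome.
#'
#' @param report A `qc_report` / `qc_filter_result`.
#' @return A ggplot object.
#' @export
plot_qc_metrics <- function(report) {
  d <- report$droplets |>
    dplyr::mutate(outcome = ifelse(.data$pass, "pass", "fail")) |>
    dplyr::select("barcode", "outcome", "total_umi", "n_genes",
                  "mito_fraction", "mouse_fraction") |>
    tidyr::pivot_longer(c("total_umi", "n_genes", "mito_fraction",
                          "mouse_fraction"),
                        names_to = "metric", values_to = "value")
  if (all(d$value[d$metric == "mouse_fraction"] == 0))
    d <- d[d$metric != "mouse_fraction", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$value,
                                  fill = .data$outcome)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-droplet QC metrics by filter outcome") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-type-pair expression correlation
#'
#' @param object A `concordance_report`.
#' @param ... Ignored.
#' @return A ggplot object showing R-squared for every type pair; the
#'   diagonal carries the matched-type values.
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object$correlations,
                  ggplot2::aes(x = .data$type_a, y = .data$type_b,
                               fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$r_squared)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = expression(R^2)) +
    ggplot2::labs(x = object$provenance$modality_a,
                  y = object$provenance$modality_b,
                  title = "Per-cell-type expression correlation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of matched-type top-N gene overlap
#'
#' @param report A `concordance_report`.
#' @return A ggplot object (overlap fraction by N, per cell type).
#' @export
plot_top_overlap <- function(report) {
  d <- report$top_overlap |>
    dplyr::filter(.data$type_a == .data$type_b)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_top),
                                  y = 100 * .data$overlap_fraction,
                                  fill = .data$type_a)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "top N genes", y = "fractional overlap (%)",
                  fill = "cell type",
                  title = "Top-N gene overlap within cell types") +
    ggplot2::theme_minimal()
}
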