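#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a QC report
#'
#' @param x A `qc_report` from [run_droplet_qc()] (or `qc_filter_result`
#'   from [apply_qc_filters()]).
#' @param ... Ignored.
#' @return The per-droplet tibble of metrics and filter decisions.
#' @export
tidy.qc_report <- function(x, ...) x$droplets

#' @export
tidy.qc_filter_result <- function(x, ...) x$droplets

#' One-row summary of a QC report
#'
#' @inheritParams tidy.qc_report
#' @return A one-row tibble: droplets in/out, per-stage removals, median UMI
#'   and gene counts, and mean mito/mouse fractions of passing droplets.
#' @export
glance.qc_report <- function(x, ...) {
  d <- x$droplets
  pass <- d[d$pass, ]
  removed <- stats::setNames(as.list(x$tally$removed),
                             paste0("removed_", x$tally$stage))
  tibble::as_tibble(c(list(
    n_droplets_in = nrow(d),
    n_droplets_out = nrow(pass),
    n_genes_out = nrow(x$matrix$genes)),
    removed,
    list(median_umi = stats::median(pass$total_umi),
         median_genes = stats::median(pass$n_genes),
         mean_mito_fraction = mean(pass$mito_fraction),
         mean_mouse_fraction = mean(pass$mouse_fraction))))
}

#' @export
glance.qc_filter_result <- glance.qc_report

#' Tidy a concordance report
#'
#' @param x A `concordance_report`.
#' @param table Which component to return: the per-type-pair correlations,
#'   the top-N overlap table, the enrichment table, or the gene-set overlap.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.concordance_report <- function(x, table = c("correlations",
                                                 "top_overlap", "enrichment",
                                                 "overlap"), ...) {
  table <- match.arg(table)
  switch(table,
         correlations = x$correlations,
         top_overlap = x$top_overlap,
         enrichment = x$enrichment$table,
         overlap = x$overlap)
}

#' One-row summary of a concordance report
#'
#' @param x A `concordance_report`.
#' @param ... Ignored.
#' @return A one-row tibble: set overlap, mean matched/mismatched R-squared,
#'   mean matched top-100 overlap, number of enriched genes and the lncRNA
#'   share among them.
#' @export
glance.concordance_report <- function(x, ...) {
  matched <- x$correlations[x$correlations$type_a == x$correlations$type_b, ]
  mism <- x$correlations[x$correlations$type_a != x$correlations$type_b, ]
  top100 <- x$top_overlap[x$top_overlap$type_a == x$top_overlap$type_b &
                            x$top_overlap$n_top == min(x$top_overlap$n_top), ]
  bp <- x$enrichment$biotype_proportions
  lnc <- bp$proportion[bp$biotype == "lncRNA"]
  tibble::tibble(
    jaccard = x$overlap$jaccard,
    pct_of_smaller = x$overlap$pct_of_smaller,
    mean_matched_r2 = mean(matched$r_squared),
    mean_mismatched_r2 = mean(mism$r_squared),
    mean_matched_top100 = mean(top100$overlap_fraction),
    n_enriched = x$enrichment$n_enriched,
    lncRNA_share_enriched = if (length(lnc)) lnc else 0
  )
}
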