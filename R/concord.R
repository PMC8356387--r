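#' Detected gene set
#'
#' A gene counts as expressed in a droplet if it has at least one UMI; the
#' detected set contains genes expressed in at least `min_cells` droplets.
#'
#' @param matrix A QC-filtered [droplet_matrix()].
#' @param min_cells Minimum number of droplets (default 3).
#' @return Character vector of gene ids.
#' @export
detected_gene_set <- function(matrix, min_cells = 3L) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  n_det <- Matrix::rowSums(matrix$counts > 0)
  matrix$genes$gene_id[n_det >= min_cells]
}

#' Overlap statistics for two gene sets
#'
#' Reports both the Jaccard index and the intersection as a percentage of
#' the smaller set, since "percent overlap" figures in the literature can
#' mean either.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return A one-row tibble: `n_a`, `n_b`, `n_intersect`, `jaccard`,
#'   `pct_of_smaller`.
#' @export
gene_set_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  ni <- length(intersect(a, b))
  nu <- length(union(a, b))
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_intersect = ni,
    jaccard = if (nu == 0) 0 else ni / nu,
    pct_of_smaller = if (min(length(a), length(b)) == 0) 0 else
      100 * ni / min(length(a), length(b))
  )
}

#' Per-cell-type mean expression profiles
#'
#' Mean ln counts per gene over the droplets assigned to each type. Types
#' with fewer than 10 droplets are flagged; types with none are omitted
#' with a warning.
#'
#' @param ln An ln matrix (genes x droplets) with gene-id rownames.
#' @param labels A `type_labels` tibble (from [annotate_clusters()]) or a
#'   character vector of types per droplet.
#' @return A tibble: `gene_id`, `type`, `mean_ln`, `n_droplets`,
#'   `low_n` flag.
#' @export
celltype_mean_profiles <- function(ln, labels) {
  types <- if (is.data.frame(labels))
    labels$type[match(colnames(ln), labels$barcode)] else labels
  stopifnot(length(types) == ncol(ln))
  if (anyNA(types)) {
    warning("droplets without a type label are omitted", call. = FALSE)
  }
  lv <- unique(stats::na.omit(types))
  purrr::map_dfr(lv, function(t) {
    idx <- which(types == t)
    if (length(idx) == 0) {
      warning("type with no droplets omitted: ", t, call. = FALSE)
      return(NULL)
    }
    tibble::tibble(gene_id = rownames(ln), type = t,
                   mean_ln = unname(Matrix::rowMeans(ln[, idx, drop = FALSE])),
                   n_droplets = length(idx),
                   low_n = length(idx) < 10)
  })
}

# means tibble (long) -> genes x types matrix
means_to_matrix <- function(means) {
  wide <- tidyr::pivot_wider(means[, c("gene_id", "type", "mean_ln")],
                             names_from = "type", values_from = "mean_ln")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

#' All-vs-all per-type expression correlation between two datasets
#'
#' For each pair of cell types (one from each dataset), regresses dataset
#' B's mean ln counts per gene on dataset A's over the shared gene space,
#' reporting the Pearson correlation `r`, `R^2 = r^2`, and the two-sided
#' p-value for `r != 0`.
#'
#' @param means_a,means_b Tibbles from [celltype_mean_profiles()].
#' @param genes Optional gene ids to restrict to (e.g. the intersection of
#'   detected sets); default uses all shared genes.
#' @param min_genes Fewer shared genes than this is an error.
#' @return A tibble: `type_a`, `type_b`, `n_genes`, `r`, `r_squared`, `p`.
#' @export
profile_correlation <- function(means_a, means_b, genes = NULL,
                                min_genes = 10L) {
  ma <- means_to_matrix(means_a)
  mb <- means_to_matrix(means_b)
  shared <- intersect(rownames(ma), rownames(mb))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < min_genes)
    stop(sprintf("fewer than %d shared genes between datasets", min_genes),
         call. = FALSE)
  ma <- ma[shared, , drop = FALSE]
  mb <- mb[shared, , drop = FALSE]
  n <- length(shared)
  grid <- tidyr::expand_grid(type_a = colnames(ma), type_b = colnames(mb))
  grid |>
    dplyr::mutate(purrr::map2_dfr(.data$type_a, .data$type_b, function(ta, tb) {
      r <- stats::cor(ma[, ta], mb[, tb])
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      tibble::tibble(n_genes = n, r = r, r_squared = r^2,
                     p = 2 * stats::pt(-abs(tstat), df = n - 2))
    }))
}

#' Fractional overlap of top-N genes per cell type
#'
#' Ranks genes within each cell type by mean ln counts (descending, ties
#' broken by gene id) in each dataset and reports
#' `|topN(A) intersect topN(B)| / N` for each N, for every pair of types
#' (matched-type rows are the headline statistic; cross-type rows support
#' specificity checks).
#'
#' @param means_a,means_b Tibbles from [celltype_mean_profiles()].
#' @param n_list Top-N sizes.
#' @param genes Optional gene-id restriction.
#' @return A tibble: `type_a`, `type_b`, `n_top`, `overlap_fraction`.
#' @export
top_gene_overlap <- function(means_a, means_b,
                             n_list = c(100L, 200L, 500L, 1000L),
                             genes = NULL) {
  ma <- means_to_matrix(means_a)
  mb <- means_to_matrix(means_b)
  shared <- intersect(rownames(ma), rownames(mb))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  ma <- ma[shared, , drop = FALSE]
  mb <- mb[shared, , drop = FALSE]
  feasible <- n_list[n_list <= length(shared)]
  if (length(feasible) < length(n_list))
    warning("fewer shared genes than some requested N; computing feasible N only",
            call. = FALSE)
  rank_top <- function(m, type, n) {
    ord <- order(-m[, type], rownames(m))
    rownames(m)[ord[seq_len(n)]]
  }
  grid <- tidyr::expand_grid(type_a = colnames(ma), type_b = colnames(mb),
                             n_top = as.integer(feasible))
  grid$overlap_fraction <- purrr::pmap_dbl(grid, function(type_a, type_b, n_top) {
    length(intersect(rank_top(ma, type_a, n_top),
                     rank_top(mb, type_b, n_top))) / n_top
  })
  grid
}

#' Per-gene detection rates
#'
#' Percentage of droplets in which each gene has at least one UMI.
#'
#' @param matrix A QC-filtered [droplet_matrix()].
#' @return A tibble: `gene_id`, `n_detected`, `n_droplets`, `pct_detected`.
#' @export
detection_rates <- function(matrix) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  n <- ncol(matrix$counts)
  if (n == 0) stop("matrix has zero droplets", call. = FALSE)
  nd <- as.integer(Matrix::rowSums(matrix$counts > 0))
  tibble::tibble(gene_id = matrix$genes$gene_id, n_detected = nd,
                 n_droplets = n, pct_detected = 100 * nd / n)
}

#' Nuclear detection-rate enrichment with biotype breakdown
#'
#' Compares per-gene detection percentages between a nucleus dataset and a
#' whole-cell dataset. A gene is called enriched in the nucleus data when
#' its detection fold-change (`pct_sn / pct_sc`) exceeds `fold` and the
#' two-proportion test on detection counts is significant at FDR `alpha`
#' (Benjamini-Hochberg across genes). Genes detected in the nucleus data
#' but never in the whole-cell data get infinite fold-change and are
#' flagged. Biotype proportions are reported over the enriched genes.
#'
#' @param rates_sn,rates_sc Tibbles from [detection_rates()] over the same
#'   gene space.
#' @param annotations Gene table with `gene_id` and `biotype`.
#' @param fold Fold-change threshold (enrichment requires strictly greater).
#' @param alpha FDR level.
#' @param method `"z"` for the two-proportion z-test (no continuity
#'   correction) or `"fisher"` for Fisher's exact test.
#' @return A list of class `detection_enrichment`: `table` (per-gene tibble
#'   sorted by fold change), `biotype_proportions`, `n_enriched`, and the
#'   thresholds used.
#' @export
detection_enrichment <- function(rates_sn, rates_sc, annotations,
                                 fold = 1.5, alpha = 0.05,
                                 method = c("z", "fisher")) {
  method <- match.arg(method)
  if (!setequal(rates_sn$gene_id, rates_sc$gene_id))
    stop("gene spaces of the two datasets do not match", call. = FALSE)
  sc <- rates_sc[match(rates_sn$gene_id, rates_sc$gene_id), ]

  x1 <- rates_sn$n_detected; n1 <- rates_sn$n_droplets
  x2 <- sc$n_detected; n2 <- sc$n_droplets
  p1 <- x1 / n1; p2 <- x2 / n2

  if (method == "z") {
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- ifelse(se > 0, (p1 - p2) / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- vapply(seq_along(x1), function(i)
      stats::fisher.test(matrix(c(x1[i], n1[i] - x1[i],
                                  x2[i], n2[i] - x2[i]), 2))$p.value,
      numeric(1))
  }
  q <- stats::p.adjust(p, "BH")

  fc <- ifelse(p2 > 0, p1 / p2, ifelse(p1 > 0, Inf, NaN))
  tab <- tibble::tibble(
    gene_id = rates_sn$gene_id,
    pct_sn = 100 * p1, pct_sc = 100 * p2,
    fold_change = fc,
    infinite_fold = is.infinite(fc),
    p = p, q = q,
    enriched = !is.nan(fc) & fc > fold & q <= alpha
  ) |>
    dplyr::left_join(annotations[, c("gene_id", "biotype")], by = "gene_id") |>
    dplyr::arrange(dplyr::desc(.data$fold_change), dplyr::desc(.data$pct_sn))

  enr <- tab[tab$enriched, ]
  biotype_proportions <- enr |>
    dplyr::count(.data$biotype, name = "n") |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))

  structure(list(table = tab, biotype_proportions = biotype_proportions,
                 n_enriched = nrow(enr), fold = fold, alpha = alpha,
                 method = method),
            class = "detection_enrichment")
}

#' Full concordance report between two datasets
#'
#' Computes the detected-gene-set overlap, the all-vs-all per-type
#' expression correlations (restricted to the intersection of detected
#' sets), the top-N overlap table, and the nucleus detection enrichment
#' with biotype breakdown (dataset A is treated as the nucleus side).
#'
#' @param matrix_a,matrix_b QC-filtered [droplet_matrix()] objects (A =
#'   nucleus side of the enrichment comparison).
#' @param labels_a,labels_b `type_labels` tibbles for each dataset.
#' @param min_cells Detected-set threshold.
#' @param n_list Top-N sizes.
#' @param fold,alpha Enrichment thresholds.
#' @return A list of class `concordance_report`: `overlap`, `correlations`,
#'   `top_overlap`, `enrichment`, `provenance`.
#' @export
concordance_report <- function(matrix_a, matrix_b, labels_a, labels_b,
                               min_cells = 3L,
                               n_list = c(100L, 200L, 500L, 1000L),
                               fold = 1.5, alpha = 0.05) {
  set_a <- detected_gene_set(matrix_a, min_cells)
  set_b <- detected_gene_set(matrix_b, min_cells)
  overlap <- gene_set_overlap(set_a, set_b)
  shared <- intersect(set_a, set_b)

  ln_a <- normalize_ln(matrix_a)
  ln_b <- normalize_ln(matrix_b)
  means_a <- celltype_mean_profiles(ln_a, labels_a)
  means_b <- celltype_mean_profiles(ln_b, labels_b)
  correlations <- profile_correlation(means_a, means_b, genes = shared)
  top_overlap <- top_gene_overlap(means_a, means_b, n_list, genes = shared)

  shared_all <- intersect(matrix_a$genes$gene_id, matrix_b$genes$gene_id)
  rates_a <- detection_rates(matrix_a[shared_all, ])
  rates_b <- detection_rates(matrix_b[shared_all, ])
  enrichment <- detection_enrichment(rates_a, rates_b, matrix_a$genes,
                                     fold = fold, alpha = alpha)

  structure(list(
    overlap = overlap, correlations = correlations,
    top_overlap = top_overlap, enrichment = enrichment,
    provenance = list(modality_a = matrix_a$modality,
                      modality_b = matrix_b$modality,
                      min_cells = min_cells, n_list = n_list,
                      fold = fold, alpha = alpha)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>", x$provenance$modality_a, "vs",
      x$provenance$modality_b, "\n")
  cat(sprintf("  detected genes: %d vs %d, %.1f%% of smaller set shared (Jaccard %.3f)\n",
              x$overlap$n_a, x$overlap$n_b, x$overlap$pct_of_smaller,
              x$overlap$jaccard))
  matched <- dplyr::filter(x$correlations, .data$type_a == .data$type_b)
  cat(sprintf("  matched-type R^2: %s\n",
              paste(sprintf("%s=%.2f", matched$type_a, matched$r_squared),
                    collapse = ", ")))
  cat(sprintf("  enriched genes (fold > %.1f, q <= %.2f): %d\n",
              x$enrichment$fold, x$enrichment$alpha, x$enrichment$n_enriched))
  invisible(x)
}
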