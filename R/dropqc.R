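#' Quality-control thresholds
#'
#' Defaults follow standard droplet QC practice for islet sc/snRNA-seq:
#' genes kept if detected in at least 3 droplets; droplets kept if at least
#' 200 genes are detected; droplets removed if more than 20% of UMIs are
#' mitochondrial; xenograft nuclei additionally require at least 1000 UMIs
#' and 500 detected genes and at most 25% mouse UMIs (removal is strict:
#' a droplet at exactly 20% mito or 25% mouse survives). Empty droplets are
#' those with posterior probability of the low-count mixture component above
#' 0.5.
#'
#' @param min_cells_per_gene Keep genes detected (>= 1 UMI) in at least this
#'   many surviving droplets.
#' @param min_genes_per_droplet Keep droplets with at least this many
#'   detected genes.
#' @param max_mito_fraction Remove droplets with mito fraction strictly
#'   greater than this.
#' @param max_mouse_fraction Remove graft droplets with mouse-UMI fraction
#'   strictly greater than this.
#' @param graft_min_umi,graft_min_genes Additional graft-mode floors; a
#'   droplet strictly below either is removed.
#' @param empty_posterior_cutoff Posterior cutoff for the empty-droplet call.
#' @param expected_doublet_rate Fraction of droplets flagged as doublets.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3L,
                          min_genes_per_droplet = 200L,
                          max_mito_fraction = 0.20,
                          max_mouse_fraction = 0.25,
                          graft_min_umi = 1000L,
                          graft_min_genes = 500L,
                          empty_posterior_cutoff = 0.5,
                          expected_doublet_rate = 0.05) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_droplet >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            max_mouse_fraction >= 0, max_mouse_fraction <= 1,
            graft_min_umi >= 0, graft_min_genes >= 0,
            empty_posterior_cutoff >= 0, empty_posterior_cutoff <= 1)
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_genes_per_droplet = as.integer(min_genes_per_droplet),
                 max_mito_fraction = max_mito_fraction,
                 max_mouse_fraction = max_mouse_fraction,
                 graft_min_umi = as.integer(graft_min_umi),
                 graft_min_genes = as.integer(graft_min_genes),
                 empty_posterior_cutoff = empty_posterior_cutoff,
                 expected_doublet_rate = expected_doublet_rate),
            class = "qc_thresholds")
}

#' Per-droplet QC metrics
#'
#' Computes, per droplet: total UMIs, number of detected genes (>= 1 UMI),
#' mitochondrial UMI fraction, and mouse-gene UMI fraction. All-zero
#' droplets get fractions of 0 by convention.
#'
#' @param matrix A [droplet_matrix()] whose gene table has `is_mito` and
#'   `species` columns.
#' @return A tibble with columns `barcode`, `total_umi`, `n_genes`,
#'   `mito_fraction`, `mouse_fraction`.
#' @export
compute_droplet_metrics <- function(matrix) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  for (field in c("is_mito", "species")) {
    if (!field %in% names(matrix$genes))
      stop("gene annotations lack required field: ", field, call. = FALSE)
  }
  m <- matrix$counts
  total <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mito <- Matrix::colSums(m[matrix$genes$is_mito, , drop = FALSE])
  mouse <- Matrix::colSums(m[matrix$genes$species == "mouse", , drop = FALSE])
  safe <- ifelse(total > 0, total, 1)
  tibble::tibble(
    barcode = matrix$barcodes,
    total_umi = as.integer(total),
    n_genes = as.integer(ngene),
    mito_fraction = as.numeric(mito / safe),
    mouse_fraction = as.numeric(mouse / safe)
  )
}

#' Call empty droplets and estimate the ambient expression profile
#'
#' Fits a Gaussian mixture (1 or 2 components, chosen by BIC) to
#' `ln(total UMI + 1)`. When a genuinely bimodal fit is found — two
#' components whose means are at least 2 ln-units apart — droplets whose
#' posterior membership in the low component exceeds
#' `empty_posterior_cutoff` are flagged empty, and the ambient profile is
#' the normalized pooled counts of the flagged droplets. A unimodal or
#' degenerate fit flags nothing (with a warning) and the ambient profile
#' falls back to the pooled counts of the lowest 1% of droplets by UMI.
#'
#' @param matrix A [droplet_matrix()] with at least 100 droplets.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `empty` (logical per droplet), `empty_posterior`
#'   (numeric per droplet), and `ambient_profile` (probability vector over
#'   genes, sums to 1).
#' @export
call_empty_droplets <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  n <- ncol(matrix$counts)
  if (n < 100) stop("need at least 100 droplets to call empties", call. = FALSE)
  total <- Matrix::colSums(matrix$counts)
  x <- log(total + 1)

  # Mclust resolves mclustBIC in the caller's frame; bind it locally
  mclustBIC <- mclust::mclustBIC
  fit <- suppressWarnings(
    mclust::Mclust(x, G = 1:2, modelNames = c("E", "V"), verbose = FALSE))
  degenerate <- is.null(fit) || fit$G == 1 ||
    abs(diff(range(fit$parameters$mean))) < 2

  if (degenerate) {
    warning("no separable low-count mode; flagging no droplets as empty",
            call. = FALSE)
    empty <- rep(FALSE, n)
    post <- rep(0, n)
  } else {
    low <- which.min(fit$parameters$mean)
    post <- fit$z[, low]
    empty <- post > thresholds$empty_posterior_cutoff
  }

  if (any(empty)) {
    pooled <- Matrix::rowSums(matrix$counts[, empty, drop = FALSE])
  } else {
    k <- max(1L, ceiling(0.01 * n))
    bottom <- order(total)[seq_len(k)]
    pooled <- Matrix::rowSums(matrix$counts[, bottom, drop = FALSE])
  }
  ambient_profile <- as.numeric(pooled) / sum(pooled)
  names(ambient_profile) <- matrix$genes$gene_id
  list(empty = empty, empty_posterior = as.numeric(post),
       ambient_profile = ambient_profile)
}

# Multinomial log-likelihood profile maximizer for one droplet: the rho in
# [0, 1] maximizing sum(c * log((1 - rho) * centroid + rho * ambient)).
fit_ambient_rho <- function(counts, centroid, ambient) {
  nz <- which(counts > 0)
  cts <- counts[nz]
  m <- centroid[nz]
  a <- ambient[nz]
  ll <- function(rho) sum(cts * log(pmax((1 - rho) * m + rho * a, 1e-300)))
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  cand[which.max(vapply(cand, ll, numeric(1)))]
}

#' Estimate per-droplet ambient-RNA fractions
#'
#' Coarse-groups droplets by k-means on the top principal components of
#' depth-scaled ln counts and forms each group's expression centroid. A raw
#' centroid is itself contaminated by ambient RNA, so each group's mean
#' contamination is first anchored on its ambient-dominated genes — genes
#' whose centroid mass is far below their ambient mass (markers of other
#' cell types), whose counts in this group can only be ambient — and
#' subtracted from the centroid. Each droplet's ambient fraction `rho` then
#' maximizes the multinomial likelihood of its counts under
#' `(1 - rho) * centroid + rho * ambient_profile` (1-D search on `[0, 1]`).
#'
#' @param matrix A [droplet_matrix()] of non-empty droplets.
#' @param ambient_profile Probability vector over the same genes.
#' @param n_groups Number of k-means groups.
#' @param seed Integer seed for the grouping.
#' @return A tibble with `barcode` and `ambient_estimate`.
#' @export
estimate_ambient_fractions <- function(matrix, ambient_profile, n_groups = 5L,
                                       seed = 1L) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  if (n_groups < 1) stop("n_groups must be >= 1", call. = FALSE)
  if (length(ambient_profile) != nrow(matrix$counts))
    stop("ambient_profile length does not match the gene space", call. = FALSE)
  m <- matrix$counts
  n <- ncol(m)
  n_groups <- min(n_groups, n)

  set.seed(seed)
  ln <- ln_cp10k(m)
  pcs <- droplet_pcs(ln, n_pcs = min(10L, n - 1L, nrow(m)))
  grp <- if (n_groups == 1L) rep(1L, n) else
    stats::kmeans(pcs, centers = n_groups, nstart = 5, iter.max = 50)$cluster

  centroids <- vapply(seq_len(n_groups), function(g) {
    s <- Matrix::rowSums(m[, grp == g, drop = FALSE])
    as.numeric(s) / sum(s)
  }, numeric(nrow(m)))

  # anchor each group's mean contamination on genes the group does not
  # natively express (centroid mass far below ambient mass), then purify
  for (g in seq_len(n_groups)) {
    anchored <- ambient_profile > 0 & centroids[, g] < 0.25 * ambient_profile
    if (sum(ambient_profile[anchored]) > 1e-4) {
      r_g <- min(0.5, sum(centroids[anchored, g]) /
                   sum(ambient_profile[anchored]))
      purified <- pmax(centroids[, g] - r_g * ambient_profile, 0)
      if (sum(purified) > 0) centroids[, g] <- purified / sum(purified)
    }
  }

  dense <- as.matrix(m)
  rho <- vapply(seq_len(n), function(d)
    fit_ambient_rho(dense[, d], centroids[, grp[d]], ambient_profile),
    numeric(1))
  tibble::tibble(barcode = matrix$barcodes, ambient_estimate = rho)
}

#' Flag probable doublets with an artificial-doublet kNN score
#'
#' Synthesizes artificial doublets (half the number of real droplets) by
#' summing the counts of random droplet pairs, embeds real and artificial
#' droplets in a shared principal-component space of depth-scaled ln counts,
#' and scores each real droplet by the fraction of artificial droplets among
#' its k = 40 nearest neighbours. The top `expected_doublet_rate` quantile of
#' real droplets by score is flagged (ties broken by barcode order).
#'
#' @param matrix A [droplet_matrix()] of at least 50 non-empty droplets.
#' @param thresholds A [qc_thresholds()]; uses `expected_doublet_rate`.
#' @param seed Integer seed.
#' @param k Number of nearest neighbours.
#' @param artificial_fraction Artificial doublets as a fraction of real
#'   droplets.
#' @return A tibble with `barcode`, `doublet_score`, `doublet`.
#' @export
flag_doublets <- function(matrix, thresholds = qc_thresholds(), seed = 1L,
                          k = 40L, artificial_fraction = 0.5) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  rate <- thresholds$expected_doublet_rate
  if (rate < 0 || rate >= 0.5)
    stop("expected_doublet_rate must be in [0, 0.5)", call. = FALSE)
  m <- matrix$counts
  n <- ncol(m)
  if (n < 50) stop("need at least 50 droplets to score doublets", call. = FALSE)

  set.seed(seed)
  n_art <- ceiling(artificial_fraction * n)
  p1 <- sample(n, n_art, replace = TRUE)
  p2 <- sample(n, n_art, replace = TRUE)
  same <- p1 == p2
  p2[same] <- (p2[same] %% n) + 1L
  art <- m[, p1, drop = FALSE] + m[, p2, drop = FALSE]

  combined <- methods::cbind2(m, art)
  ln <- ln_cp10k(combined)
  pcs <- droplet_pcs(ln, n_pcs = min(25L, ncol(combined) - 1L, nrow(combined)))
  k <- min(k, n + n_art - 1L)
  nn <- RANN::nn2(pcs, pcs[seq_len(n), , drop = FALSE], k = k + 1L)$nn.idx
  score <- vapply(seq_len(n), function(d) {
    nb <- setdiff(nn[d, ], d)[seq_len(k)]
    mean(nb > n)
  }, numeric(1))

  n_flag <- round(rate * n)
  flagged <- rep(FALSE, n)
  if (n_flag > 0) {
    ord <- order(-score, seq_len(n))
    flagged[ord[seq_len(n_flag)]] <- TRUE
  }
  tibble::tibble(barcode = matrix$barcodes, doublet_score = score,
                 doublet = flagged)
}

#' Apply the QC filter cascade
#'
#' Removal order: empty droplets, then flagged doublets, then per-droplet
#' thresholds (detected genes >= `min_genes_per_droplet`; mitochondrial
#' fraction retained up to and including `max_mito_fraction` — removal is
#' strictly greater; in graft mode additionally total UMI >=
#' `graft_min_umi`, detected genes >= `graft_min_genes`, and mouse fraction
#' <= `max_mouse_fraction`), then (graft mode) removal of all mouse genes,
#' and finally the gene filter: genes detected (>= 1 UMI) in at least
#' `min_cells_per_gene` of the surviving droplets. The gene filter runs last
#' so "detected in at least N cells" refers to droplets that survived.
#'
#' @param matrix A [droplet_matrix()].
#' @param metrics Per-droplet metrics from [compute_droplet_metrics()]
#'   computed on `matrix`; recomputed if `NULL`.
#' @param thresholds A [qc_thresholds()].
#' @param graft_mode Apply the xenograft-specific filters?
#' @param empty Optional logical per droplet (from [call_empty_droplets()]).
#' @param doublet Optional logical per droplet (from [flag_doublets()]).
#' @return A list of class `qc_filter_result`: `matrix` (filtered),
#'   `droplets` (tibble of per-droplet filter decisions), `tally` (tibble of
#'   per-stage removals), `genes_removed`, `thresholds`.
#' @export
apply_qc_filters <- function(matrix, metrics = NULL,
                             thresholds = qc_thresholds(),
                             graft_mode = FALSE, empty = NULL,
                             doublet = NULL) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  if (is.null(metrics)) metrics <- compute_droplet_metrics(matrix)
  stopifnot(nrow(metrics) == ncol(matrix$counts))
  n <- ncol(matrix$counts)
  if (is.null(empty)) empty <- rep(FALSE, n)
  if (is.null(doublet)) doublet <- rep(FALSE, n)

  keep <- rep(TRUE, n)
  tally <- list()
  drop_stage <- function(keep, fail, stage) {
    removed <- keep & fail
    tally[[stage]] <<- sum(removed)
    keep & !fail
  }

  keep <- drop_stage(keep, empty, "empty")
  keep <- drop_stage(keep, doublet, "doublet")
  fail_droplet <- metrics$n_genes < thresholds$min_genes_per_droplet |
    metrics$mito_fraction > thresholds$max_mito_fraction
  if (graft_mode) {
    fail_droplet <- fail_droplet |
      metrics$total_umi < thresholds$graft_min_umi |
      metrics$n_genes < thresholds$graft_min_genes |
      metrics$mouse_fraction > thresholds$max_mouse_fraction
  }
  keep <- drop_stage(keep, fail_droplet, "droplet_thresholds")

  out <- matrix[, keep]
  if (graft_mode) {
    human <- out$genes$species != "mouse"
    out <- out[human, ]
  }
  detected_in <- Matrix::rowSums(out$counts > 0)
  gene_keep <- detected_in >= thresholds$min_cells_per_gene
  genes_removed <- out$genes$gene_id[!gene_keep]
  out <- out[gene_keep, ]
  if (ncol(out$counts) == 0)
    warning("no droplets survive QC filtering", call. = FALSE)

  droplets <- metrics
  droplets$empty <- empty
  droplets$doublet <- doublet
  droplets$fail_thresholds <- fail_droplet
  droplets$pass <- keep

  structure(list(
    matrix = out,
    droplets = droplets,
    tally = tibble::tibble(stage = names(tally),
                           removed = as.integer(unlist(tally))),
    genes_removed = genes_removed,
    thresholds = thresholds,
    graft_mode = graft_mode
  ), class = "qc_filter_result")
}

#' Run the full droplet QC stage
#'
#' Convenience wrapper chaining [compute_droplet_metrics()],
#' [call_empty_droplets()], [flag_doublets()] and
#' [estimate_ambient_fractions()] (both on non-empty droplets), and
#' [apply_qc_filters()].
#'
#' @inheritParams apply_qc_filters
#' @param seed Integer seed for the stochastic sub-steps.
#' @return A list of class `qc_report`: the `qc_filter_result` fields plus a
#'   `metrics` tibble carrying `empty_posterior`, `ambient_estimate` and
#'   `doublet_score` per droplet, and the `ambient_profile`.
#' @export
run_droplet_qc <- function(matrix, thresholds = qc_thresholds(),
                           graft_mode = FALSE, seed = 1L) {
  metrics <- compute_droplet_metrics(matrix)
  empties <- call_empty_droplets(matrix, thresholds)
  nonempty <- matrix[, !empties$empty]
  doub <- flag_doublets(nonempty, thresholds, seed = seed)
  amb <- estimate_ambient_fractions(nonempty, empties$ambient_profile,
                                    seed = seed)

  metrics$empty_posterior <- empties$empty_posterior
  metrics$doublet_score <- 0
  metrics$doublet_score[!empties$empty] <- doub$doublet_score
  metrics$ambient_estimate <- NA_real_
  metrics$ambient_estimate[!empties$empty] <- amb$ambient_estimate
  doublet <- rep(FALSE, ncol(matrix$counts))
  doublet[!empties$empty] <- doub$doublet

  res <- apply_qc_filters(matrix, metrics, thresholds, graft_mode,
                          empty = empties$empty, doublet = doublet)
  res$ambient_profile <- empties$ambient_profile
  class(res) <- c("qc_report", class(res))
  res
}
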