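#' Analysis parameters for clustering and annotation
#'
#' @param n_pcs Number of principal components (default 25, matching common
#'   practice for islet droplet data).
#' @param k_neighbors Neighbours for the kNN/SNN graph.
#' @param resolution Louvain modularity resolution.
#' @param expressed_min_umi A gene counts as expressed in a droplet at this
#'   many UMIs (default 1).
#' @param annotation_min_correlation Clusters whose best reference
#'   correlation falls below this are flagged low-confidence.
#' @param marker_alpha FDR level for cluster markers.
#' @param n_variable_genes Genes kept for dimensionality reduction.
#' @param seed Integer seed.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(n_pcs = 25L, k_neighbors = 15L, resolution = 1.0,
                            expressed_min_umi = 1L,
                            annotation_min_correlation = 0.5,
                            marker_alpha = 0.05, n_variable_genes = 2000L,
                            seed = 1L) {
  stopifnot(n_pcs >= 2, k_neighbors >= 2, resolution > 0,
            annotation_min_correlation >= -1, annotation_min_correlation <= 1)
  structure(list(n_pcs = as.integer(n_pcs),
                 k_neighbors = as.integer(k_neighbors),
                 resolution = resolution,
                 expressed_min_umi = as.integer(expressed_min_umi),
                 annotation_min_correlation = annotation_min_correlation,
                 marker_alpha = marker_alpha,
                 n_variable_genes = as.integer(n_variable_genes),
                 seed = as.integer(seed)),
            class = "analysis_params")
}

#' Natural-log transform of UMI counts
#'
#' `ln(1 + count)`, the scale on which all concordance statistics are
#' computed. With `depth_scale = TRUE`, counts are first scaled to 10,000
#' per droplet (the variant used for clustering, where library-size
#' differences would otherwise dominate the leading components).
#'
#' @param matrix A [droplet_matrix()] or a non-negative count matrix.
#' @param depth_scale Scale each droplet to 10,000 counts first?
#' @return A sparse matrix of ln values with gene/barcode dimnames.
#' @export
normalize_ln <- function(matrix, depth_scale = FALSE) {
  m <- if (inherits(matrix, "droplet_matrix")) matrix$counts else
    methods::as(methods::as(methods::as(matrix, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  if (any(m@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (depth_scale) ln_cp10k(m) else {
    out <- m
    out@x <- log1p(out@x)
    out
  }
}

#' Reduce dimensionality and cluster droplets
#'
#' Selects the most variable genes, standardizes them, projects droplets
#' onto the top principal components, builds a shared-nearest-neighbour
#' graph (Jaccard-weighted k-nearest neighbours), and partitions it by
#' Louvain modularity optimization at the requested resolution. Cluster ids
#' are integers starting at 0, ordered by decreasing size (ties broken by
#' the smallest contained barcode).
#'
#' @param ln A depth-scaled ln matrix from
#'   `normalize_ln(x, depth_scale = TRUE)` (genes x droplets).
#' @param params An [analysis_params()].
#' @return A tibble with `barcode` and `cluster`.
#' @export
reduce_and_cluster <- function(ln, params = analysis_params()) {
  n <- ncol(ln)
  if (n < params$k_neighbors + 1)
    stop("need more droplets than k_neighbors to cluster", call. = FALSE)
  barcodes <- colnames(ln)
  if (is.null(barcodes)) barcodes <- as.character(seq_len(n))

  set.seed(params$seed)
  pcs <- droplet_pcs(ln, n_pcs = min(params$n_pcs, n - 1L, nrow(ln)),
                     n_var_genes = params$n_variable_genes)
  if (all(abs(pcs) < 1e-12)) {
    return(tibble::tibble(barcode = barcodes, cluster = 0L))
  }

  k <- min(params$k_neighbors, n - 1L)
  nn <- RANN::nn2(pcs, pcs, k = k + 1L)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  snn <- methods::as(shared, "TsparseMatrix")
  jac <- snn@x / (2 * (k + 1L) - snn@x)
  keep <- jac >= 1 / 15 & snn@i < snn@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = snn@i[keep] + 1L, to = snn@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- igraph::cluster_louvain(g, resolution = params$resolution)
  memb <- igraph::membership(comm)[as.character(seq_len(n))]

  # relabel by decreasing size, smallest barcode breaks ties; ids 0-based
  tab <- tibble::tibble(raw = as.integer(memb), barcode = barcodes)
  ord <- tab |>
    dplyr::group_by(.data$raw) |>
    dplyr::summarise(size = dplyr::n(), first_bc = min(.data$barcode)) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_bc)
  relabel <- stats::setNames(seq_len(nrow(ord)) - 1L, ord$raw)
  tibble::tibble(barcode = barcodes,
                 cluster = as.integer(relabel[as.character(tab$raw)]))
}

#' Annotate clusters against reference cell-type profiles
#'
#' Computes each cluster's centroid (mean ln counts per gene) and assigns
#' the cell type whose reference centroid it correlates with most strongly
#' (Pearson, over the shared gene space). Reference centroids are the
#' ln-transformed type profiles scaled to a nominal library of 10,000.
#' Clusters whose best correlation falls below
#' `annotation_min_correlation` are still labelled by the argmax but flagged
#' low-confidence.
#'
#' @param ln An ln matrix (genes x droplets) with gene-id rownames.
#' @param clusters Tibble from [reduce_and_cluster()] (or an integer vector
#'   per droplet).
#' @param reference A [build_reference_profiles()] object, or a numeric
#'   genes-x-types matrix of reference centroids (ln scale) with gene-id
#'   rownames.
#' @param params An [analysis_params()].
#' @return A tibble of class `type_labels`: `barcode`, `cluster`, `type`,
#'   `correlation`, `low_confidence`.
#' @export
annotate_clusters <- function(ln, clusters, reference,
                              params = analysis_params()) {
  if (is.data.frame(clusters)) {
    stopifnot(all(c("barcode", "cluster") %in% names(clusters)))
    cl <- clusters$cluster[match(colnames(ln), clusters$barcode)]
  } else cl <- clusters
  stopifnot(length(cl) == ncol(ln))

  ref <- if (inherits(reference, "reference_profiles"))
    log1p(reference$profiles * 1e4) else as.matrix(reference)
  shared <- intersect(rownames(ln), rownames(ref))
  if (length(shared) == 0)
    stop("no genes shared between data and reference", call. = FALSE)

  lns <- ln[shared, , drop = FALSE]
  refs <- ref[shared, , drop = FALSE]
  ids <- sort(unique(cl))
  cent <- vapply(ids, function(cid)
    Matrix::rowMeans(lns[, cl == cid, drop = FALSE]), numeric(length(shared)))
  cors <- stats::cor(cent, refs)  # clusters x types
  best <- apply(cors, 1, which.max)
  assign <- tibble::tibble(
    cluster = ids,
    type = colnames(refs)[best],
    correlation = cors[cbind(seq_along(ids), best)],
    low_confidence = cors[cbind(seq_along(ids), best)] <
      params$annotation_min_correlation
  )
  out <- tibble::tibble(barcode = colnames(ln), cluster = cl) |>
    dplyr::left_join(assign, by = "cluster")
  class(out) <- c("type_labels", class(out))
  out
}

# Tie term sum(t^3 - t) over tied groups, per gene row.
rank_tie_terms <- function(dense) {
  apply(dense, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
}

#' Per-cluster marker genes (one-sided Wilcoxon rank-sum)
#'
#' For every gene and cluster, tests whether ln expression in the cluster is
#' stochastically greater than in all other droplets (normal-approximation
#' rank-sum with tie and continuity corrections), adjusts p-values by
#' Benjamini-Hochberg within each cluster, and flags markers with
#' `q <= marker_alpha` and positive effect (difference of mean ln values).
#'
#' @param ln An ln matrix (genes x droplets) with gene-id rownames.
#' @param clusters Tibble from [reduce_and_cluster()] or an integer vector.
#' @param params An [analysis_params()].
#' @return A tibble: `gene_id`, `cluster`, `effect`, `p`, `q`, `is_marker`,
#'   sorted by cluster then q.
#' @export
find_cluster_markers <- function(ln, clusters, params = analysis_params()) {
  if (is.data.frame(clusters)) {
    cl <- clusters$cluster[match(colnames(ln), clusters$barcode)]
  } else cl <- clusters
  stopifnot(length(cl) == ncol(ln))
  ids <- sort(unique(cl))
  if (length(ids) < 2) {
    warning("fewer than 2 clusters; no markers computed", call. = FALSE)
    return(tibble::tibble(gene_id = character(), cluster = integer(),
                          effect = numeric(), p = numeric(), q = numeric(),
                          is_marker = logical()))
  }
  dense <- as.matrix(ln)
  n <- ncol(dense)
  ranks <- t(apply(dense, 1, rank))
  ties <- rank_tie_terms(dense)

  res <- purrr::map_dfr(ids, function(cid) {
    ing <- cl == cid
    n1 <- sum(ing); n2 <- n - n1
    u <- rowSums(ranks[, ing, drop = FALSE]) - n1 * (n1 + 1) / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - ties / (n * (n - 1)))
    z <- ifelse(sigma2 > 0, (u - n1 * n2 / 2 - 0.5) / sqrt(sigma2), 0)
    p <- stats::pnorm(z, lower.tail = FALSE)
    effect <- rowMeans(dense[, ing, drop = FALSE]) -
      rowMeans(dense[, !ing, drop = FALSE])
    tibble::tibble(gene_id = rownames(dense), cluster = cid,
                   effect = unname(effect), p = unname(p),
                   q = stats::p.adjust(unname(p), "BH"))
  })
  res$is_marker <- res$q <= params$marker_alpha & res$effect > 0
  dplyr::arrange(res, .data$cluster, .data$q, dplyr::desc(.data$effect))
}

#' Cluster and annotate a QC-filtered dataset
#'
#' Convenience wrapper: depth-scaled ln normalization, clustering,
#' annotation against reference profiles, and marker detection.
#'
#' @param matrix A QC-filtered [droplet_matrix()].
#' @param reference See [annotate_clusters()].
#' @param params An [analysis_params()].
#' @return A list with `labels` (a `type_labels` tibble), `markers`, and
#'   `ln` (the undepth-scaled ln matrix used for concordance statistics).
#' @export
annotate_dataset <- function(matrix, reference, params = analysis_params()) {
  ln_cluster <- normalize_ln(matrix, depth_scale = TRUE)
  clusters <- reduce_and_cluster(ln_cluster, params)
  ln <- normalize_ln(matrix, depth_scale = FALSE)
  labels <- annotate_clusters(ln, clusters, reference, params)
  markers <- find_cluster_markers(ln, clusters, params)
  list(labels = labels, markers = markers, ln = ln)
}
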