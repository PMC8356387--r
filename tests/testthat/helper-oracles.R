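# Independent brute-force re-application of the filter cascade, written as
# plain loops over a dense matrix; the oracle for apply_qc_filters.
brute_force_filter <- function(dm, thresholds, graft_mode, empty, doublet) {
  cnt <- as.matrix(dm$counts)
  n <- ncol(cnt)
  keep <- rep(TRUE, n)
  for (d in seq_len(n)) {
    if (empty[d] || doublet[d]) { keep[d] <- FALSE; next }
    total <- sum(cnt[, d])
    ngenes <- sum(cnt[, d] >= 1)
    mito <- if (total > 0) sum(cnt[dm$genes$is_mito, d]) / total else 0
    mouse <- if (total > 0)
      sum(cnt[dm$genes$species == "mouse", d]) / total else 0
    if (ngenes < thresholds$min_genes_per_droplet) keep[d] <- FALSE
    if (mito > thresholds$max_mito_fraction) keep[d] <- FALSE
    if (graft_mode) {
      if (total < thresholds$graft_min_umi) keep[d] <- FALSE
      if (ngenes < thresholds$graft_min_genes) keep[d] <- FALSE
      if (mouse > thresholds$max_mouse_fraction) keep[d] <- FALSE
    }
  }
  gene_keep <- rep(TRUE, nrow(cnt))
  if (graft_mode) gene_keep <- dm$genes$species != "mouse"
  sub <- cnt[, keep, drop = FALSE]
  for (g in which(gene_keep)) {
    if (sum(sub[g, ] >= 1) < thresholds$min_cells_per_gene)
      gene_keep[g] <- FALSE
  }
  list(barcodes = dm$barcodes[keep], gene_ids = dm$genes$gene_id[gene_keep],
       counts = cnt[gene_keep, keep, drop = FALSE])
}

random_test_matrix <- function(seed, n_droplets = 400, n_genes = 120,
                               graft = FALSE) {
  set.seed(seed)
  libs <- pmax(1, round(stats::rlnorm(n_droplets, log(80), 1.2)))
  prof <- stats::rgamma(n_genes, 0.5); prof <- prof / sum(prof)
  cnt <- vapply(libs, function(l) stats::rmultinom(1, l, prof)[, 1],
                numeric(n_genes))
  is_mito <- seq_len(n_genes) <= 6
  species <- if (graft) rep(c("human", "mouse"), c(n_genes - 30, 30)) else
    rep("human", n_genes)
  dm_from_dense(cnt, is_mito = is_mito, species = species,
                modality = if (graft) "graft_nucleus" else "whole_cell")
}

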