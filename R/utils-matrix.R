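# Shared sparse-matrix helpers: depth-scaled ln transform, variable-gene
# selection, PCA embedding of droplets.

ln_cp10k <- function(m) {
  tot <- Matrix::colSums(m)
  tot[tot == 0] <- 1
  scaled <- m %*% Matrix::Diagonal(x = 1e4 / tot)
  scaled <- methods::as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(m)
  scaled
}

row_vars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  mu2 <- Matrix::rowMeans(m^2)
  pmax(mu2 - mu^2, 0) * ncol(m) / max(1, ncol(m) - 1)
}

# Droplet scores on the top principal components of standardized
# high-variance genes. Returns an n_droplets x n_pcs matrix.
droplet_pcs <- function(ln, n_pcs = 25L, n_var_genes = 2000L) {
  v <- row_vars_sparse(ln)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_var_genes, nrow(ln)))]
  x <- t(as.matrix(ln[keep, , drop = FALSE]))
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  x <- scale(x, center = TRUE, scale = sds)
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  if (n_pcs < 1 || all(abs(x) < 1e-12)) {
    return(matrix(0, nrow(x), max(1L, n_pcs)))
  }
  pc <- stats::prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)
  pc$x
}
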