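#' Droplet count matrix container
#'
#' A `droplet_matrix` bundles a sparse gene-by-droplet UMI count matrix with
#' its gene annotation table, droplet barcodes, and a modality tag
#' (`"whole_cell"`, `"nucleus"`, or `"graft_nucleus"`). Genes are rows,
#' droplets are columns, throughout the package.
#'
#' @param counts A non-negative integer matrix or `Matrix::dgCMatrix`
#'   (genes x droplets).
#' @param genes A tibble with one row per gene. Must contain `gene_id`;
#'   `symbol`, `species`, `biotype`, `is_mito` are filled with defaults if
#'   absent (`species = "human"`, `biotype = "protein_coding"`,
#'   `is_mito = FALSE`).
#' @param barcodes Character vector of droplet barcodes, one per column.
#' @param modality Modality tag; free-form but the pipeline uses
#'   `"whole_cell"`, `"nucleus"`, `"graft_nucleus"`.
#'
#' @return An object of class `droplet_matrix`: a list with elements
#'   `counts`, `genes`, `barcodes`, `modality`.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(3, 5), dims = c(2, 2))
#' dm <- droplet_matrix(m, tibble::tibble(gene_id = c("g1", "g2")), c("bc1", "bc2"))
#' dim(dm)
droplet_matrix <- function(counts, genes, barcodes, modality = "whole_cell") {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts@x != round(counts@x))) stop("counts must be integers", call. = FALSE)
  genes <- tibble::as_tibble(genes)
  if (!"gene_id" %in% names(genes)) stop("`genes` must have a gene_id column", call. = FALSE)
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  if (!"species" %in% names(genes)) genes$species <- "human"
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  if (!"is_mito" %in% names(genes)) genes$is_mito <- FALSE
  if (nrow(genes) != nrow(counts)) {
    stop(sprintf("genes table has %d rows but counts has %d gene rows",
                 nrow(genes), nrow(counts)), call. = FALSE)
  }
  if (length(barcodes) != ncol(counts)) {
    stop(sprintf("barcodes has %d entries but counts has %d droplet columns",
                 length(barcodes), ncol(counts)), call. = FALSE)
  }
  rownames(counts) <- genes$gene_id
  colnames(counts) <- barcodes
  structure(
    list(counts = counts, genes = genes, barcodes = as.character(barcodes),
         modality = modality),
    class = "droplet_matrix"
  )
}

#' @export
dim.droplet_matrix <- function(x) dim(x$counts)

#' @export
print.droplet_matrix <- function(x, ...) {
  cat(sprintf("<droplet_matrix> %s: %d genes x %d droplets (%d nonzero)\n",
              x$modality, nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  sp <- table(x$genes$species)
  cat("  species:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a droplet matrix
#'
#' @param x A [droplet_matrix()].
#' @param i Gene index (integer, logical, or gene-id character).
#' @param j Droplet index (integer, logical, or barcode character).
#' @param ... Ignored.
#' @return A `droplet_matrix` restricted to the selected genes/droplets.
#' @export
`[.droplet_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$genes$gene_id)
  if (is.character(j)) j <- match(j, x$barcodes)
  droplet_matrix(x$counts[i, j, drop = FALSE], x$genes[i, , drop = FALSE],
                 x$barcodes[j], x$modality)
}
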