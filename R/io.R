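find_tenx_file <- function(dir, base) {
  for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop("missing ", base, "[.gz] in ", dir, call. = FALSE)
}

#' Read a 10x-style count bundle
#'
#' Reads `matrix.mtx[.gz]`, `features.tsv[.gz]`, `barcodes.tsv[.gz]` from a
#' directory into a [droplet_matrix()]. Species is inferred from `hg-`/`mm-`
#' feature-id prefixes when present (the prefix is stripped from the stored
#' gene id), otherwise from a `gene_annotations.tsv` sidecar, else assumed
#' human. The mitochondrial flag comes from the sidecar or an `MT-` symbol
#' prefix.
#'
#' @param dir Directory containing the triplet.
#' @param modality Modality tag for the result.
#' @return A [droplet_matrix()].
#' @export
read_tenx_bundle <- function(dir, modality = "whole_cell") {
  mtx_file <- find_tenx_file(dir, "matrix.mtx")
  feat_file <- find_tenx_file(dir, "features.tsv")
  bc_file <- find_tenx_file(dir, "barcodes.tsv")

  m <- if (grepl("\\.gz$", mtx_file)) {
    con <- gzfile(mtx_file)
    # readMM consumes and invalidates the connection; closing is best-effort
    on.exit(tryCatch(close(con), error = function(e) NULL), add = TRUE)
    Matrix::readMM(con)
  } else Matrix::readMM(mtx_file)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (length(m@x) && any(m@x != round(m@x)))
    stop("matrix.mtx contains non-integer values", call. = FALSE)

  feats <- readr::read_tsv(feat_file, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  barcodes <- sub("\t.*", "", readr::read_lines(bc_file, progress = FALSE))
  if (nrow(feats) != nrow(m))
    stop(sprintf("features.tsv has %d rows but matrix.mtx declares %d genes",
                 nrow(feats), nrow(m)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes.tsv has %d rows but matrix.mtx declares %d droplets",
                 length(barcodes), ncol(m)), call. = FALSE)

  ids <- feats[[1]]
  symbols <- if (ncol(feats) >= 2) feats[[2]] else ids
  prefixed <- grepl("^(hg|mm)-", ids)
  species <- rep(NA_character_, length(ids))
  if (any(prefixed)) {
    species <- ifelse(grepl("^mm-", ids), "mouse", "human")
    ids <- sub("^(hg|mm)-", "", ids)
    symbols <- sub("^(hg|mm)-", "", symbols)
  }
  genes <- tibble::tibble(gene_id = ids, symbol = symbols)

  sidecar <- file.path(dir, "gene_annotations.tsv")
  if (file.exists(sidecar)) {
    ann <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
    genes <- dplyr::left_join(genes, ann, by = intersect(c("gene_id", "symbol"),
                                                         names(ann)))
  }
  if (!"species" %in% names(genes) || anyNA(genes$species)) {
    fallback <- if (any(prefixed)) species else "human"
    genes$species <- if ("species" %in% names(genes))
      dplyr::coalesce(genes$species, fallback) else fallback
  }
  if (!"is_mito" %in% names(genes))
    genes$is_mito <- startsWith(genes$symbol, "MT-")
  droplet_matrix(m, genes, barcodes, modality)
}

#' Write a 10x-style count bundle
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, integer-valued, genes as
#' rows, 1-based indices), `features.tsv`, `barcodes.tsv`, and a
#' `gene_annotations.tsv` sidecar. When the matrix mixes species (a
#' xenograft bundle), feature ids are prefixed `hg-`/`mm-`. Optionally
#' writes a simulation `truth.tsv` and the generator config as
#' `sim_config.yaml`.
#'
#' @param matrix A [droplet_matrix()].
#' @param dir Output directory (created if needed).
#' @param gzip Gzip the triplet files?
#' @param truth Optional truth tibble to write alongside.
#' @param config Optional [sim_config()] to record as YAML.
#' @return `dir`, invisibly.
#' @export
write_tenx_bundle <- function(matrix, dir, gzip = FALSE, truth = NULL,
                              config = NULL) {
  stopifnot(inherits(matrix, "droplet_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)

  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(matrix$counts, mtx)
  # declare the integer field the 10x dialect uses
  lines <- readLines(mtx)
  lines[1] <- sub(" real ", " integer ", lines[1])
  writeLines(lines, mtx)

  mixed <- length(unique(matrix$genes$species)) > 1
  ids <- if (mixed) {
    paste0(ifelse(matrix$genes$species == "mouse", "mm-", "hg-"),
           matrix$genes$gene_id)
  } else matrix$genes$gene_id
  feats <- tibble::tibble(ids, matrix$genes$symbol, "Gene Expression")
  readr::write_tsv(feats, file.path(dir, "features.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(tibble::tibble(matrix$barcodes),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(matrix$genes, file.path(dir, "gene_annotations.tsv"),
                   progress = FALSE)
  if (!is.null(truth))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "sim_config.yaml"))

  if (gzip) {
    for (base in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
      src <- file.path(dir, base)
      con <- gzfile(paste0(src, ".gz"), "wb")
      writeLines(readLines(src), con)
      close(con)
      unlink(src)
    }
  }
  invisible(dir)
}
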