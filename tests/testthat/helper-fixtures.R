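# Lazily computed fixtures shared across test files (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default paired simulation taken through QC and annotation.
default_paired <- function() fixture("default_paired", {
  cfg <- sim_config(seed = 101L)
  sim <- simulate_paired_experiment(cfg)
  qc_wc <- suppressWarnings(run_droplet_qc(sim$whole_cell$matrix, seed = 111L))
  qc_nu <- suppressWarnings(run_droplet_qc(sim$nucleus$matrix, seed = 112L))
  ty_wc <- annotate_dataset(qc_wc$matrix, sim$profiles,
                            analysis_params(seed = 121L))
  ty_nu <- annotate_dataset(qc_nu$matrix, sim$profiles,
                            analysis_params(seed = 122L))
  list(cfg = cfg, sim = sim, qc_wc = qc_wc, qc_nu = qc_nu,
       ty_wc = ty_wc, ty_nu = ty_nu)
})

default_concordance <- function() fixture("default_concordance", {
  fx <- default_paired()
  suppressWarnings(concordance_report(
    fx$qc_nu$matrix, fx$qc_wc$matrix, fx$ty_nu$labels, fx$ty_wc$labels))
})

# Small two-type configuration for clustering / doublet checks.
two_type_config <- function(n = 600L, doublet_rate = 0, n_empty = 0L,
                            seed = 5L) {
  sim_config(cell_type_names = c("alpha", "beta"),
             cell_type_proportions = c(0.5, 0.5),
             doublet_rate = doublet_rate, n_empty_droplets = n_empty,
             n_droplets = c(whole_cell = n, nucleus = n, graft_nucleus = n),
             seed = seed)
}

# Build a droplet_matrix directly from a dense count matrix.
dm_from_dense <- function(counts, is_mito = NULL, species = NULL,
                          biotype = NULL, modality = "whole_cell") {
  ng <- nrow(counts)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(ng)),
    is_mito = is_mito %||% rep(FALSE, ng),
    species = species %||% rep("human", ng),
    biotype = biotype %||% rep("protein_coding", ng))
  droplet_matrix(Matrix::Matrix(counts, sparse = TRUE), genes,
                 sprintf("bc%04d", seq_len(ncol(counts))), modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
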