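#' Configuration for the synthetic droplet-count generator
#'
#' Builds the parameter set for simulating paired whole-cell / nucleus (and
#' optionally xenograft-nucleus) droplet UMI data. Defaults emulate the QC
#' profile of cultured human islets assayed by both droplet scRNA-seq and
#' snRNA-seq: ambient contamination around 5.9% in whole cells, 1.4% in
#' nuclei and 4.6% in graft nuclei; mitochondrial UMI shares of 4.2% (cells)
#' and 2.7% (nuclei); and a 3-fold nuclear retention of lncRNA transcripts.
#'
#' @param n_genes_human,n_genes_mouse Number of human / mouse genes.
#' @param biotype_fractions Named proportions over
#'   `c("protein_coding", "lncRNA", "mito")`; must sum to 1. The default puts
#'   13 genes in the mitochondrial block at `n_genes_human = 2000`.
#' @param cell_type_names,cell_type_proportions Cell-type labels and their
#'   sampling probabilities (sum to 1). Defaults cover the major islet types.
#' @param markers_per_type Number of marker genes boosted per type (disjoint
#'   across types).
#' @param marker_fold Multiplicative boost applied to a type's marker genes
#'   before renormalization.
#' @param marker_exclusivity Factor (in `[0, 1]`) applied to a type's marker
#'   genes in every *other* type's profile, making markers near-exclusive to
#'   their own type as in real tissue (insulin transcripts in an alpha cell
#'   are essentially ambient-only).
#' @param library_size_logmean,library_size_logsd Named per-modality
#'   log-normal parameters for droplet library size.
#' @param ambient_level Named per-modality mean ambient fraction in `[0, 1)`;
#'   per-droplet fractions are Beta-distributed around this mean with
#'   concentration 50.
#' @param doublet_rate Fraction of non-empty droplets that are doublets.
#' @param n_empty_droplets Number of empty (ambient-only) droplets appended
#'   per modality.
#' @param empty_size_logmean,empty_size_logsd Log-normal parameters for empty
#'   droplet library sizes.
#' @param mito_target Named per-modality mitochondrial UMI share the adjusted
#'   expression profiles are calibrated to.
#' @param lncRNA_retention_factor Multiplier (>= 1) on lncRNA profile mass in
#'   nucleus modalities.
#' @param lncRNA_abundance_meanlog,lncRNA_abundance_sdlog Log-normal
#'   parameters for lncRNA baseline abundance, on the same scale as the
#'   protein-coding gamma draws (mean 0.5). lncRNAs are far lower expressed
#'   than mRNAs; the defaults centre whole-cell lncRNA detection rates
#'   around 10%, the mid-range where nuclear lncRNAs are observed
#'   (NEAT1-like genes around 35%, MEG3-like around 7%).
#' @param mouse_beta_params Two-component Beta mixture for the per-droplet
#'   mouse-UMI fraction in the graft modality: a list with numeric vectors
#'   `shape1`, `shape2` (length 2, clean then contaminated component) and
#'   `weight` (mixture weights summing to 1). Default modes are ~0.05
#'   (clean) and ~0.6 (contaminated) with 10% contaminated droplets.
#' @param n_droplets Named per-modality count of non-empty droplets.
#' @param seed Integer seed; sub-streams for each modality are derived from
#'   it by fixed offsets.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_genes_human = 2000,
    n_genes_mouse = 300,
    biotype_fractions = c(protein_coding = 1 - 0.15 - 13 / 2000,
                          lncRNA = 0.15, mito = 13 / 2000),
    cell_type_names = c("alpha", "beta", "delta", "PP", "ductal", "other"),
    cell_type_proportions = c(0.35, 0.30, 0.10, 0.05, 0.10, 0.10),
    markers_per_type = 20,
    marker_fold = 8,
    marker_exclusivity = 0.02,
    library_size_logmean = c(whole_cell = log(6000), nucleus = log(4000),
                             graft_nucleus = log(3500)),
    library_size_logsd = c(whole_cell = 0.35, nucleus = 0.35,
                           graft_nucleus = 0.35),
    ambient_level = c(whole_cell = 0.0587, nucleus = 0.0142,
                      graft_nucleus = 0.046),
    doublet_rate = 0.05,
    n_empty_droplets = 200,
    empty_size_logmean = log(50),
    empty_size_logsd = 0.5,
    mito_target = c(whole_cell = 0.042, nucleus = 0.027,
                    graft_nucleus = 0.015),
    lncRNA_retention_factor = 3,
    lncRNA_abundance_meanlog = log(0.02),
    lncRNA_abundance_sdlog = 1.2,
    mouse_beta_params = list(shape1 = c(4, 7), shape2 = c(58, 5),
                             weight = c(0.9, 0.1)),
    n_droplets = c(whole_cell = 1000, nucleus = 1000, graft_nucleus = 1000),
    seed = 1L) {
  cfg <- list(
    n_genes_human = as.integer(n_genes_human),
    n_genes_mouse = as.integer(n_genes_mouse),
    biotype_fractions = biotype_fractions,
    cell_type_names = cell_type_names,
    cell_type_proportions = cell_type_proportions,
    markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold,
    marker_exclusivity = marker_exclusivity,
    library_size_logmean = library_size_logmean,
    library_size_logsd = library_size_logsd,
    ambient_level = ambient_level,
    doublet_rate = doublet_rate,
    n_empty_droplets = as.integer(n_empty_droplets),
    empty_size_logmean = empty_size_logmean,
    empty_size_logsd = empty_size_logsd,
    mito_target = mito_target,
    lncRNA_retention_factor = lncRNA_retention_factor,
    lncRNA_abundance_meanlog = lncRNA_abundance_meanlog,
    lncRNA_abundance_sdlog = lncRNA_abundance_sdlog,
    mouse_beta_params = mouse_beta_params,
    n_droplets = n_droplets,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes_human > 0, cfg$n_genes_mouse >= 0,
            cfg$markers_per_type > 0, cfg$marker_fold > 0,
            cfg$n_empty_droplets >= 0, cfg$lncRNA_retention_factor >= 1)
  if (abs(sum(cfg$biotype_fractions) - 1) > 1e-8)
    stop("biotype_fractions must sum to 1", call. = FALSE)
  if (!setequal(names(cfg$biotype_fractions),
                c("protein_coding", "lncRNA", "mito")))
    stop("biotype_fractions must be named protein_coding, lncRNA, mito",
         call. = FALSE)
  if (length(cfg$cell_type_names) != length(cfg$cell_type_proportions))
    stop("cell_type_names and cell_type_proportions lengths differ",
         call. = FALSE)
  if (abs(sum(cfg$cell_type_proportions) - 1) > 1e-8)
    stop("cell_type_proportions must sum to 1", call. = FALSE)
  if (any(cfg$cell_type_proportions < 0))
    stop("cell_type_proportions must be non-negative", call. = FALSE)
  if (cfg$marker_exclusivity < 0 || cfg$marker_exclusivity > 1)
    stop("marker_exclusivity must be in [0, 1]", call. = FALSE)
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)", call. = FALSE)
  if (any(cfg$ambient_level < 0 | cfg$ambient_level >= 1))
    stop("ambient_level must be in [0, 1)", call. = FALSE)
  if (any(cfg$mito_target < 0 | cfg$mito_target >= 1))
    stop("mito_target must be in [0, 1)", call. = FALSE)
  if (abs(sum(cfg$mouse_beta_params$weight) - 1) > 1e-8)
    stop("mouse_beta_params$weight must sum to 1", call. = FALSE)
  if (any(cfg$n_droplets <= 0))
    stop("n_droplets must be positive", call. = FALSE)
  invisible(cfg)
}

# Canonical islet marker symbols given to the first markers of the matching
# configured type; the first symbol per type is the "primary" marker whose
# baseline abundance is pinned to the genome-wide maximum so that, boosted,
# it dominates the type profile (as INS does a beta-cell transcriptome).
canonical_markers <- list(
  alpha  = "GCG",
  beta   = c("INS", "ABCC8", "SLC30A8", "MAFA"),
  delta  = "SST",
  PP     = "PPY",
  ductal = c("CFTR", "SOX9", "KRT19")
)

canonical_lncRNAs <- c("NEAT1", "MEG3", "COX10-AS1", "MCM3AP-AS1")

mito_symbols_13 <- c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L",
                     "MT-ND5", "MT-ND6", "MT-CO1", "MT-CO2", "MT-CO3",
                     "MT-ATP6", "MT-ATP8", "MT-CYB")

#' Build per-type reference expression profiles
#'
#' Draws a shared baseline gene-abundance vector (symmetric Dirichlet,
#' concentration 0.5), assigns disjoint marker-gene sets to each configured
#' cell type, multiplies each type's markers by `marker_fold`, and
#' renormalizes, yielding one probability vector over human genes per type.
#' Canonical islet markers (INS for beta, GCG for alpha, SST for delta, PPY
#' for PP, CFTR/SOX9/KRT19 for ductal) are named and assigned when those type
#' names are configured; well-known nuclear lncRNAs (NEAT1, MEG3, COX10-AS1,
#' MCM3AP-AS1) name the first lncRNA genes. A separate Dirichlet profile over
#' mouse genes supports the xenograft modality.
#'
#' @param config A [sim_config()].
#' @return An object of class `reference_profiles`: list with `profiles`
#'   (genes x types probability matrix, columns sum to 1), `genes` (tibble of
#'   gene annotations with a `marker_of` column), and `mouse_profile`.
#' @export
build_reference_profiles <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes_human
  types <- config$cell_type_names
  nt <- length(types)

  n_mito <- round(config$biotype_fractions[["mito"]] * ng)
  n_lnc <- round(config$biotype_fractions[["lncRNA"]] * ng)
  n_pc <- ng - n_mito - n_lnc
  if (n_pc < config$markers_per_type * nt) {
    stop(sprintf(paste0("too few protein-coding genes (%d) for %d markers x ",
                        "%d types"), n_pc, config$markers_per_type, nt),
         call. = FALSE)
  }

  mito_sym <- if (n_mito == 13) mito_symbols_13 else
    sprintf("MT-G%02d", seq_len(n_mito))
  lnc_sym <- c(canonical_lncRNAs[seq_len(min(n_lnc, length(canonical_lncRNAs)))],
               sprintf("LINC%05d", seq_len(max(0, n_lnc - length(canonical_lncRNAs)))))
  pc_sym <- sprintf("GENE%05d", seq_len(n_pc))

  genes <- tibble::tibble(
    symbol = c(pc_sym, lnc_sym, mito_sym),
    biotype = rep(c("protein_coding", "lncRNA", "mito"), c(n_pc, n_lnc, n_mito)),
    species = "human",
    is_mito = rep(c(FALSE, FALSE, TRUE), c(n_pc, n_lnc, n_mito)),
    marker_of = NA_character_
  )

  # disjoint marker sets drawn from the protein-coding block
  marker_idx <- matrix(sample(n_pc, config$markers_per_type * nt),
                       nrow = config$markers_per_type)
  colnames(marker_idx) <- types
  for (t in types) {
    idx <- marker_idx[, t]
    genes$marker_of[idx] <- t
    canon <- canonical_markers[[t]]
    if (!is.null(canon)) {
      k <- min(length(canon), length(idx))
      genes$symbol[idx[seq_len(k)]] <- canon[seq_len(k)]
    }
  }
  genes$gene_id <- genes$symbol

  # shared baseline abundance; heavy right tail mimics real UMI skew
  base <- stats::rgamma(ng, shape = 0.5)
  lnc_genes <- genes$biotype == "lncRNA"
  base[lnc_genes] <- stats::rlnorm(sum(lnc_genes),
                                   config$lncRNA_abundance_meanlog,
                                   config$lncRNA_abundance_sdlog)
  # pin each type's primary marker to the genome-wide max baseline so the
  # boosted marker is the top gene of its profile by construction
  for (t in types) {
    if (!is.null(canonical_markers[[t]])) base[marker_idx[1, t]] <- max(base)
  }

  profiles <- matrix(base, nrow = ng, ncol = nt,
                     dimnames = list(genes$gene_id, types))
  for (t in types) {
    profiles[marker_idx[, t], t] <- profiles[marker_idx[, t], t] * config$marker_fold
    # markers are near-exclusive: downweight them in every other type
    profiles[marker_idx[, t], setdiff(types, t)] <-
      profiles[marker_idx[, t], setdiff(types, t)] * config$marker_exclusivity
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/")

  mouse_profile <- NULL
  if (config$n_genes_mouse > 0) {
    mp <- stats::rgamma(config$n_genes_mouse, shape = 0.5)
    mouse_profile <- mp / sum(mp)
    names(mouse_profile) <- sprintf("Mgene%05d", seq_len(config$n_genes_mouse))
  }

  structure(list(profiles = profiles, genes = genes,
                 mouse_profile = mouse_profile, config = config),
            class = "reference_profiles")
}

# Rescale type profiles for a modality: boost lncRNA retention in nucleus
# modalities, then calibrate the mitochondrial UMI share to mito_target.
modality_profiles <- function(profiles, config, modality) {
  pr <- profiles$profiles
  genes <- profiles$genes
  if (modality %in% c("nucleus", "graft_nucleus")) {
    lnc <- genes$biotype == "lncRNA"
    pr[lnc, ] <- pr[lnc, , drop = FALSE] * config$lncRNA_retention_factor
    pr <- sweep(pr, 2, colSums(pr), "/")
  }
  target <- config$mito_target[[modality]]
  mito <- genes$is_mito
  if (any(mito) && target > 0) {
    s <- colSums(pr[mito, , drop = FALSE])
    pr[mito, ] <- sweep(pr[mito, , drop = FALSE], 2, target / s, "*")
    pr[!mito, ] <- sweep(pr[!mito, , drop = FALSE], 2,
                         (1 - target) / (1 - s), "*")
  }
  pr
}

#' Simulate one droplet modality
#'
#' Draws singlet, doublet, and empty droplets for one modality. Each
#' non-empty droplet's expected gene distribution is
#' `(1 - rho) * pi_type + rho * pi_ambient`, with the per-droplet ambient
#' fraction `rho` Beta-distributed around the modality's ambient level
#' (concentration 50) and `pi_ambient` the abundance-weighted mixture of the
#' modality-adjusted type profiles. Counts are one multinomial draw of a
#' log-normal library size. Doublets average two distinct type profiles and
#' inflate the library size 1.6-fold; empties draw small libraries from the
#' ambient profile. The graft modality appends mouse genes with a per-droplet
#' mouse-UMI fraction from a two-component Beta mixture.
#'
#' @param config A [sim_config()].
#' @param profiles [build_reference_profiles()] output built from `config`.
#' @param modality One of `"whole_cell"`, `"nucleus"`, `"graft_nucleus"`.
#' @param seed Integer seed for this modality's stream.
#' @return A list with `matrix` (a [droplet_matrix()]) and `truth` (tibble:
#'   `barcode`, `kind`, `type`, `type2`, `true_ambient_fraction`,
#'   `true_mouse_fraction`, `library_size`).
#' @export
simulate_modality <- function(config, profiles, modality, seed) {
  if (!modality %in% c("whole_cell", "nucleus", "graft_nucleus"))
    stop("unknown modality: ", modality, call. = FALSE)
  n_real <- config$n_droplets[[modality]]
  if (is.null(n_real) || n_real <= 0)
    stop("n_droplets must be positive for modality ", modality, call. = FALSE)
  set.seed(seed)

  pr <- modality_profiles(profiles, config, modality)
  types <- config$cell_type_names
  props <- config$cell_type_proportions
  ambient <- as.vector(pr %*% props)

  n_doub <- round(config$doublet_rate * n_real)
  n_sing <- n_real - n_doub
  n_empty <- config$n_empty_droplets
  n_tot <- n_real + n_empty

  kind <- rep(c("singlet", "doublet", "empty"), c(n_sing, n_doub, n_empty))
  type1 <- rep(NA_character_, n_tot)
  type2 <- rep(NA_character_, n_tot)
  type1[seq_len(n_sing)] <- sample(types, n_sing, replace = TRUE, prob = props)
  if (n_doub > 0) {
    for (d in seq_len(n_doub)) {
      pair <- if (length(types) >= 2) sample(types, 2, prob = props) else
        rep(types, 2)
      type1[n_sing + d] <- pair[1]
      type2[n_sing + d] <- pair[2]
    }
  }

  amean <- config$ambient_level[[modality]]
  rho <- c(stats::rbeta(n_real, amean * 50, (1 - amean) * 50), rep(1, n_empty))

  lib <- c(stats::rlnorm(n_sing, config$library_size_logmean[[modality]],
                         config$library_size_logsd[[modality]]),
           1.6 * stats::rlnorm(n_doub, config$library_size_logmean[[modality]],
                               config$library_size_logsd[[modality]]),
           stats::rlnorm(n_empty, config$empty_size_logmean,
                         config$empty_size_logsd))
  lib <- pmax(1L, as.integer(round(lib)))

  graft <- modality == "graft_nucleus"
  mouse_frac <- numeric(n_tot)
  if (graft) {
    bp <- config$mouse_beta_params
    comp <- sample(seq_along(bp$weight), n_tot, replace = TRUE, prob = bp$weight)
    mouse_frac <- stats::rbeta(n_tot, bp$shape1[comp], bp$shape2[comp])
  }

  ng_h <- nrow(pr)
  ng_m <- if (graft) config$n_genes_mouse else 0L
  ng <- ng_h + ng_m

  ii <- vector("list", n_tot); xx <- vector("list", n_tot)
  for (d in seq_len(n_tot)) {
    p_h <- switch(kind[d],
      singlet = (1 - rho[d]) * pr[, type1[d]] + rho[d] * ambient,
      doublet = (1 - rho[d]) * 0.5 * (pr[, type1[d]] + pr[, type2[d]]) +
        rho[d] * ambient,
      empty = ambient)
    p <- if (graft) c((1 - mouse_frac[d]) * p_h,
                      mouse_frac[d] * profiles$mouse_profile) else p_h
    cts <- stats::rmultinom(1, lib[d], p)[, 1]
    nz <- which(cts > 0)
    ii[[d]] <- nz
    xx[[d]] <- cts[nz]
  }
  ord <- sample(n_tot)  # shuffle droplet order
  barcodes <- sprintf("%s-%05d", substr(modality, 1, 2), seq_len(n_tot))
  lens <- lengths(ii[ord])
  counts <- Matrix::sparseMatrix(
    i = unlist(ii[ord]), j = rep(seq_len(n_tot), lens),
    x = unlist(xx[ord]), dims = c(ng, n_tot))

  genes <- profiles$genes
  if (graft) {
    genes <- dplyr::bind_rows(
      genes,
      tibble::tibble(symbol = names(profiles$mouse_profile),
                     biotype = "protein_coding", species = "mouse",
                     is_mito = FALSE, marker_of = NA_character_,
                     gene_id = names(profiles$mouse_profile)))
  }

  truth <- tibble::tibble(
    barcode = barcodes,
    kind = kind[ord],
    type = type1[ord],
    type2 = type2[ord],
    true_ambient_fraction = rho[ord],
    true_mouse_fraction = mouse_frac[ord],
    library_size = lib[ord]
  )
  list(matrix = droplet_matrix(counts, genes, barcodes, modality),
       truth = truth)
}

#' Simulate a paired whole-cell / nucleus experiment
#'
#' Generates both modalities (optionally plus a graft-nucleus modality) from
#' one shared set of cell-type profiles, mirroring a paired design in which
#' one tissue sample is split between whole-cell and nucleus preparations.
#' Per-modality streams are seeded as `seed + 1` (whole_cell), `seed + 2`
#' (nucleus), `seed + 3` (graft_nucleus), so the bundle is bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Base seed; defaults to `config$seed`.
#' @param include_graft Also simulate the xenograft nucleus modality?
#' @return A list of class `paired_simulation` with elements `profiles` and
#'   one `list(matrix, truth)` per modality.
#' @export
simulate_paired_experiment <- function(config, seed = config$seed,
                                       include_graft = FALSE) {
  profiles <- build_reference_profiles(config)
  out <- list(profiles = profiles)
  out$whole_cell <- simulate_modality(config, profiles, "whole_cell", seed + 1L)
  out$nucleus <- simulate_modality(config, profiles, "nucleus", seed + 2L)
  if (include_graft)
    out$graft_nucleus <- simulate_modality(config, profiles, "graft_nucleus",
                                           seed + 3L)
  structure(out, class = "paired_simulation")
}
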