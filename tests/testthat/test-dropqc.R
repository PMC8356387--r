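test_that("droplet metrics follow the at-least-one-UMI conventions", {
  cnt <- cbind(c(8, 2, 0, 0), c(0, 0, 0, 0), c(20, 0, 0, 10))
  dm <- dm_from_dense(cnt, is_mito = c(FALSE, TRUE, FALSE, FALSE),
                      species = c("human", "human", "human", "mouse"))
  met <- compute_droplet_metrics(dm)
  expect_equal(met$total_umi, c(10L, 0L, 30L))
  expect_equal(met$n_genes, c(2L, 0L, 2L))
  expect_equal(met$mito_fraction, c(0.20, 0, 0))
  # all-zero droplet: fractions 0 by convention
  expect_equal(met$mouse_fraction[2], 0)
  # 20 human + 10 mouse UMI -> mouse fraction 1/3; 30/10 gives 0.25
  expect_equal(met$mouse_fraction[3], 1 / 3)
  dm2 <- dm_from_dense(cbind(c(30, 10)), species = c("human", "mouse"))
  expect_equal(compute_droplet_metrics(dm2)$mouse_fraction, 0.25)

  dm$genes$is_mito <- NULL
  expect_error(compute_droplet_metrics(dm), "is_mito")
})

test_that("empty-droplet calling separates a low-count mode", {
  set.seed(4)
  n_small <- 200; n_large <- 800; ng <- 100
  prof <- stats::rgamma(ng, 0.5); prof <- prof / sum(prof)
  libs <- c(round(stats::rlnorm(n_small, log(50), 0.3)),
            round(stats::rlnorm(n_large, log(5000), 0.3)))
  cnt <- vapply(libs, function(l) stats::rmultinom(1, l, prof)[, 1],
                numeric(ng))
  dm <- dm_from_dense(cnt)
  res <- call_empty_droplets(dm)
  small <- seq_len(n_small)
  expect_gte(mean(res$empty[small]), 0.95)
  expect_lte(mean(res$empty[-small]), 0.01)
  expect_equal(sum(res$ambient_profile), 1, tolerance = 1e-12)

  # unimodal input: warning, nothing flagged, bottom-1% fallback ambient
  cnt_uni <- vapply(round(stats::rlnorm(500, log(5000), 0.3)),
                    function(l) stats::rmultinom(1, l, prof)[, 1], numeric(ng))
  dm_uni <- dm_from_dense(cnt_uni)
  expect_warning(res_uni <- call_empty_droplets(dm_uni), "no separable")
  expect_equal(sum(res_uni$empty), 0)
  expect_equal(sum(res_uni$ambient_profile), 1, tolerance = 1e-12)

  expect_error(call_empty_droplets(dm_from_dense(cnt[, 1:50])), "100 droplets")
})

test_that("ambient fraction estimate hits likelihood boundaries correctly", {
  # 100 droplets exactly proportional to one profile, ambient on disjoint genes
  prof <- c(rep(0.2, 5), rep(0, 5))
  amb <- c(rep(0, 5), rep(0.2, 5))
  cnt <- matrix(rep(prof * 100, 100), nrow = 10)
  dm <- dm_from_dense(cnt)
  est <- estimate_ambient_fractions(dm, amb, n_groups = 1L, seed = 1)
  expect_equal(est$ambient_estimate, rep(0, 100))

  # droplets drawn from pure ambient score near 1
  cnt2 <- cbind(cnt, matrix(rep(amb * 200, 5), nrow = 10))
  dm2 <- dm_from_dense(cnt2)
  est2 <- estimate_ambient_fractions(dm2, amb, n_groups = 1L, seed = 1)
  expect_true(all(est2$ambient_estimate[101:105] >= 0.95))

  expect_error(estimate_ambient_fractions(dm, amb[1:5]), "gene space")
  expect_error(estimate_ambient_fractions(dm, amb, n_groups = 0), "n_groups")
})

test_that("ambient fractions are recovered on deep singlets", {
  cfg <- sim_config(
    seed = 67L,
    ambient_level = c(whole_cell = 0.05, nucleus = 0.05, graft_nucleus = 0.05),
    library_size_logmean = c(whole_cell = log(9000), nucleus = log(9000),
                             graft_nucleus = log(9000)),
    library_size_logsd = c(whole_cell = 0.25, nucleus = 0.25,
                           graft_nucleus = 0.25))
  pro <- build_reference_profiles(cfg)
  md <- simulate_modality(cfg, pro, "whole_cell", 68L)
  emp <- call_empty_droplets(md$matrix)
  ne <- md$matrix[, !emp$empty]
  est <- estimate_ambient_fractions(ne, emp$ambient_profile, n_groups = 6L,
                                    seed = 69L)
  tr <- md$truth[match(ne$barcodes, md$truth$barcode), ]
  sel <- tr$kind == "singlet" & tr$library_size >= 5000
  expect_gte(sum(sel), 500)
  expect_lte(mean(abs(est$ambient_estimate[sel] -
                        tr$true_ambient_fraction[sel])), 0.03)
})

test_that("doublet flagging respects the expected rate exactly", {
  dm <- random_test_matrix(8, n_droplets = 1000)
  expect_equal(sum(flag_doublets(dm, qc_thresholds(expected_doublet_rate = 0),
                                 seed = 1)$doublet), 0)
  fl <- flag_doublets(dm, qc_thresholds(expected_doublet_rate = 0.1), seed = 1)
  expect_equal(sum(fl$doublet), 100)
  expect_true(all(fl$doublet_score >= 0 & fl$doublet_score <= 1))
  expect_error(flag_doublets(dm, qc_thresholds(expected_doublet_rate = 0.5)),
               "expected_doublet_rate")
  expect_error(flag_doublets(dm[, 1:30], qc_thresholds()), "50 droplets")
})

test_that("heterotypic doublets are recovered with few false positives", {
  cfg <- two_type_config(n = 1000L, doublet_rate = 0.1, seed = 29L)
  pro <- build_reference_profiles(cfg)
  md <- simulate_modality(cfg, pro, "whole_cell", 30L)
  fl <- flag_doublets(md$matrix, qc_thresholds(expected_doublet_rate = 0.1),
                      seed = 31L)
  truth_doub <- md$truth$kind == "doublet"
  recall <- sum(fl$doublet & truth_doub) / sum(truth_doub)
  fpr <- sum(fl$doublet & !truth_doub) / sum(!truth_doub)
  expect_gte(recall, 0.6)
  expect_lte(fpr, 0.1)
})

test_that("the filter cascade applies the strict boundary semantics", {
  # graft worked example: d1 passes; d2 too few genes; d3 mito > 0.20;
  # d4 mouse > 0.25; all have enough UMI
  th <- qc_thresholds(min_cells_per_gene = 1, min_genes_per_droplet = 2,
                      graft_min_umi = 10, graft_min_genes = 3)
  cnt <- cbind(c(4, 4, 1, 2, 1),   # 5 genes, mito 1/12, mouse 2/12... adjust
               c(10, 4, 0, 0, 0),  # 2 genes < graft_min_genes 3
               c(6, 3, 3, 0, 0),   # mito 3/12 = 0.25 > 0.20
               c(4, 3, 1, 4, 0))   # mouse 4/12 = 1/3 > 0.25
  dm <- dm_from_dense(cnt, is_mito = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                      species = c("human", "human", "human", "mouse", "human"),
                      modality = "graft_nucleus")
  met <- compute_droplet_metrics(dm)
  expect_equal(met$mouse_fraction[1], 2 / 12)
  res <- apply_qc_filters(dm, met, th, graft_mode = TRUE)
  expect_equal(ncol(res$matrix$counts), 1)
  expect_equal(res$matrix$barcodes, dm$barcodes[1])
  # mouse genes stripped from the survivor
  expect_false(any(res$matrix$genes$species == "mouse"))

  # a droplet at exactly 20% mito survives; just above does not
  cnt2 <- cbind(rep(1, 10), rep(1, 10))
  cnt2[1, 1] <- 2   # total 11, mito 2/11 > 0.2 fails? 2/11 = 0.18 survives
  cnt2[1, 2] <- 3   # mito 3/12 = 0.25 fails
  dm2 <- dm_from_dense(rbind(c(2, 3), matrix(8, 1, 2)),
                       is_mito = c(TRUE, FALSE))
  met2 <- compute_droplet_metrics(dm2)
  expect_equal(met2$mito_fraction, c(0.2, 3 / 11))
  res2 <- apply_qc_filters(dm2, met2,
                           qc_thresholds(min_cells_per_gene = 0,
                                         min_genes_per_droplet = 0))
  expect_equal(res2$matrix$barcodes, dm2$barcodes[1])

  # a droplet at exactly 25% mouse survives in graft mode
  dm3 <- dm_from_dense(rbind(c(3, 4), matrix(9, 1, 2)),
                       species = c("mouse", "human"),
                       modality = "graft_nucleus")
  res3 <- apply_qc_filters(dm3, compute_droplet_metrics(dm3),
                           qc_thresholds(min_cells_per_gene = 0,
                                         min_genes_per_droplet = 0,
                                         graft_min_umi = 0,
                                         graft_min_genes = 0),
                           graft_mode = TRUE)
  expect_equal(res3$matrix$barcodes, dm3$barcodes[1])

  # gene detected in exactly 3 surviving droplets is retained; in 2, removed
  cnt4 <- rbind(c(1, 1, 1, 0), c(1, 1, 0, 0), c(5, 5, 5, 5))
  dm4 <- dm_from_dense(cnt4)
  res4 <- apply_qc_filters(dm4, compute_droplet_metrics(dm4),
                           qc_thresholds(min_cells_per_gene = 3,
                                         min_genes_per_droplet = 0))
  expect_setequal(res4$matrix$genes$gene_id, c("g001", "g003"))
})

test_that("filters match brute-force predicate evaluation exactly", {
  for (case in list(list(seed = 1, graft = FALSE), list(seed = 2, graft = TRUE))) {
    dm <- random_test_matrix(case$seed, n_droplets = 400, graft = case$graft)
    th <- qc_thresholds(min_cells_per_gene = 3, min_genes_per_droplet = 15,
                        max_mito_fraction = 0.2, max_mouse_fraction = 0.25,
                        graft_min_umi = 40, graft_min_genes = 20)
    set.seed(case$seed + 100)
    empty <- stats::runif(400) < 0.1
    doublet <- stats::runif(400) < 0.05
    res <- suppressWarnings(
      apply_qc_filters(dm, compute_droplet_metrics(dm), th,
                       graft_mode = case$graft, empty = empty,
                       doublet = doublet))
    oracle <- brute_force_filter(dm, th, case$graft, empty, doublet)
    expect_identical(res$matrix$barcodes, oracle$barcodes)
    expect_identical(res$matrix$genes$gene_id, oracle$gene_ids)
    expect_equal(unname(as.matrix(res$matrix$counts)),
                 unname(oracle$counts))
    # per-stage tallies account for every removed droplet
    expect_equal(sum(res$tally$removed),
                 400 - length(oracle$barcodes))
  }
})

test_that("relaxing any single threshold never removes survivors", {
  dm <- random_test_matrix(3, n_droplets = 300, graft = TRUE)
  base <- qc_thresholds(min_cells_per_gene = 3, min_genes_per_droplet = 15,
                        max_mito_fraction = 0.15, max_mouse_fraction = 0.2,
                        graft_min_umi = 40, graft_min_genes = 20)
  met <- compute_droplet_metrics(dm)
  ref <- suppressWarnings(apply_qc_filters(dm, met, base, graft_mode = TRUE))
  relaxed <- list(
    qc_thresholds(2, 15, 0.15, 0.2, 40, 20),
    qc_thresholds(3, 10, 0.15, 0.2, 40, 20),
    qc_thresholds(3, 15, 0.30, 0.2, 40, 20),
    qc_thresholds(3, 15, 0.15, 0.5, 40, 20),
    qc_thresholds(3, 15, 0.15, 0.2, 10, 20),
    qc_thresholds(3, 15, 0.15, 0.2, 40, 5))
  for (th in relaxed) {
    res <- suppressWarnings(apply_qc_filters(dm, met, th, graft_mode = TRUE))
    expect_true(all(ref$matrix$barcodes %in% res$matrix$barcodes))
    expect_true(all(ref$matrix$genes$gene_id %in% res$matrix$genes$gene_id))
  }
})

test_that("graft mouse filter agrees with true contamination components", {
  cfg <- sim_config(seed = 83L)
  pro <- build_reference_profiles(cfg)
  md <- simulate_modality(cfg, pro, "graft_nucleus", 84L)
  met <- compute_droplet_metrics(md$matrix)
  called_clean <- met$mouse_fraction <= 0.25
  truly_clean <- md$truth$true_mouse_fraction <= 0.25
  expect_gte(mean(called_clean == truly_clean), 0.99)
})

test_that("run_droplet_qc assembles a coherent report", {
  fx <- default_paired()
  rep <- fx$qc_nu
  d <- tidy(rep)
  expect_equal(nrow(d), 1200)
  expect_true(all(c("empty", "doublet", "pass", "doublet_score",
                    "ambient_estimate", "empty_posterior") %in% names(d)))
  g <- glance(rep)
  expect_equal(g$n_droplets_in - g$n_droplets_out, sum(rep$tally$removed))
  expect_true(all(d$mito_fraction >= 0 & d$mito_fraction <= 1))
  # ambient level recovered near the simulated nucleus mean
  amb <- mean(d$ambient_estimate[d$pass], na.rm = TRUE)
  expect_lt(abs(amb - fx$cfg$ambient_level[["nucleus"]]), 0.02)
})
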