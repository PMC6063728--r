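test_that("guide efficiency is the logistic of summed position weights", {
  cfg <- sim_config(n_genes = 20L, guides_per_gene = 3L,
                    n_intergenic_controls = 5L,
                    n_nontargeting_controls = 5L,
                    pwm = matrix(0, 21, 4), efficiency_noise_sd = 0,
                    seed = 3L)
  lib <- simulate_library(cfg)
  expect_true(all(lib$guides$efficiency == 0.5))

  pwm <- matrix(0, 21, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[1, "G"] <- 2
  cfg2 <- sim_config(n_genes = 60L, guides_per_gene = 4L,
                     n_intergenic_controls = 5L,
                     n_nontargeting_controls = 5L, pwm = pwm,
                     efficiency_noise_sd = 0, seed = 4L)
  lib2 <- simulate_library(cfg2)
  g1 <- substr(lib2$guides$protospacer, 1, 1) == "G"
  expect_gt(mean(lib2$guides$efficiency[g1]),
            mean(lib2$guides$efficiency[!g1]))
  # recompute efficiencies directly from the emitted sequences
  seq21 <- paste0(lib2$guides$protospacer, substr(lib2$guides$pam, 1, 1))
  expect_equal(lib2$guides$efficiency,
               plogis(ifelse(substr(seq21, 1, 1) == "G", 2, 0)))
})

test_that("library size follows the configuration arithmetic", {
  cfg <- sim_config(n_genes = 100L, guides_per_gene = 6L,
                    n_intergenic_controls = 50L,
                    n_nontargeting_controls = 50L, seed = 1L)
  lib <- simulate_library(cfg)
  expect_equal(nrow(lib$guides), 700L)
  expect_true(all(is.na(lib$guides$gene_id[lib$guides$control_class !=
                                           "targeting"])))
  expect_true(all(!is.na(lib$guides$gene_id[lib$guides$control_class ==
                                            "targeting"])))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(frac_essential = 1.2), "frac_essential")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(effect_range = c(0.5, 1)), "effect_range")
  expect_error(sim_config(pwm = matrix(0, 20, 4)), "pwm")
})

test_that("identical configuration reproduces identical outputs", {
  cfg <- small_config(seed = 9L)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a, b)
  sa <- simulate_screen(a$guides, a$truth, cfg)
  sb <- simulate_screen(b$guides, b$truth, cfg)
  expect_identical(sa$counts, sb$counts)
  ca <- simulate_companions(a$truth, cfg)
  cb <- simulate_companions(b$truth, cfg)
  expect_identical(ca, cb)
})

test_that("sequencing counts are conserved at the configured depth", {
  cfg <- small_config(seed = 5L)
  lib <- simulate_library(cfg)
  ct <- simulate_screen(lib$guides, lib$truth, cfg)
  depth <- round(cfg$read_depth_per_guide * nrow(lib$guides))
  expect_true(all(colSums(ct$counts) == depth))
})

test_that("truth satisfies its invariants", {
  lib <- simulate_library(small_config(seed = 7L))
  tr <- lib$truth$genes
  # a true fitness gene must be expressed
  expect_true(all(tr$rpkm[tr$beta < 0] >= 1))
  expect_true(all(tr$beta <= 0))
  expect_true(all(tr$copy_number >= 1))
  expect_true(all(stats::na.omit(lib$guides$gene_id) %in% tr$gene_id))
})

test_that("expected-value mode matches the closed-form dropout ratio", {
  # one fully edited guide on a beta = -1 gene does not grow (2^0 per
  # doubling), so after 45 doublings its abundance ratio against a neutral
  # guide is exactly 2^-45
  cfg <- sim_config(n_genes = 2L, guides_per_gene = 1L,
                    n_intergenic_controls = 0L,
                    n_nontargeting_controls = 0L, t0_sdlog = 0,
                    cn_spec = list(frac_by_class = c(normal = 1, mid = 0,
                                                     extreme = 0),
                                   delta = 0, damage_min_copies = 8L),
                    seed = 2L)
  lib <- simulate_library(cfg)
  lib$truth$genes$beta <- c(-1, 0)
  lib$truth$genes$essential <- c(TRUE, FALSE)
  lib$guides$efficiency <- c(1, 0)
  ct <- simulate_screen(lib$guides, lib$truth, cfg, mode = "expected")
  fin <- ct$counts[, "day45_r1"]
  t0 <- ct$counts[, "plasmid"]
  ratio <- (fin[1] / fin[2]) / (t0[1] / t0[2])
  expect_equal(unname(ratio), 2^-45, tolerance = 1e-12)
})

test_that("neutral screens center log2 fold-changes at zero", {
  # In expected-value mode an all-neutral screen has exactly zero
  # fold-change everywhere.
  cfg0 <- sim_config(n_genes = 30L, frac_essential = 0,
                     guides_per_gene = 3L, n_intergenic_controls = 10L,
                     n_nontargeting_controls = 10L,
                     cn_spec = list(frac_by_class = c(normal = 1, mid = 0,
                                                      extreme = 0),
                                    delta = 0, damage_min_copies = 8L),
                     seed = 90L)
  lib0 <- simulate_library(cfg0)
  ct0 <- simulate_screen(lib0$guides, lib0$truth, cfg0,
                         mode = "expected", n_replicates = 1L)
  lfc0 <- log2_fold_change(normalize_counts(ct0), "plasmid", "day45_r1")
  expect_equal(unname(lfc0), rep(0, length(lfc0)), tolerance = 1e-9)

  # In stochastic mode the per-guide mean carries only the second-order
  # Jensen bias of a log ratio under sampling noise (order -var/2, shared
  # by targeting and control guides), so the mean sits near zero and the
  # control-standardized gene Z stays centered.
  stats_by_seed <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 40L, frac_essential = 0,
                      guides_per_gene = 3L, n_intergenic_controls = 20L,
                      n_nontargeting_controls = 20L,
                      cells_per_guide = 300L, read_depth_per_guide = 200,
                      cn_spec = list(frac_by_class = c(normal = 1, mid = 0,
                                                       extreme = 0),
                                     delta = 0, damage_min_copies = 8L),
                      seed = 100L + s)
    lib <- simulate_library(cfg)
    ct <- simulate_screen(lib$guides, lib$truth, cfg, n_replicates = 1L)
    ctn <- normalize_counts(ct)
    lfc <- log2_fold_change(ctn, "plasmid", "day45_r1")
    sc <- score_genes(lfc, ctn$guides, n_iter = 200L, seed = s)
    c(mean_lfc = mean(lfc), mean_z = mean(sc$z))
  }, numeric(2))
  expect_lt(abs(mean(stats_by_seed["mean_lfc", ])), 0.05)
  expect_lt(abs(mean(stats_by_seed["mean_z", ])), 0.2)
})

test_that("depletion grows with effect size and with editing efficiency", {
  mk <- function(betas, effs) {
    n <- length(betas)
    cfg <- sim_config(n_genes = n, guides_per_gene = 1L,
                      n_intergenic_controls = 0L,
                      n_nontargeting_controls = 0L, t0_sdlog = 0,
                      cn_spec = list(frac_by_class = c(normal = 1, mid = 0,
                                                       extreme = 0),
                                     delta = 0, damage_min_copies = 8L),
                      seed = 3L)
    lib <- simulate_library(cfg)
    lib$truth$genes$beta <- betas
    lib$guides$efficiency <- effs
    ct <- simulate_screen(lib$guides, lib$truth, cfg, mode = "expected")
    ctn <- normalize_counts(ct)
    unname(log2_fold_change(ctn, "plasmid", "day45_r1"))
  }
  betas <- seq(-0.1, -0.9, by = -0.2)
  lfc_beta <- mk(betas, rep(0.7, length(betas)))
  expect_true(all(diff(lfc_beta) < 0))
  effs <- seq(0.2, 0.9, by = 0.1)
  lfc_eff <- mk(rep(-0.6, length(effs)), effs)
  expect_true(all(diff(lfc_eff) < 0))
})

test_that("cutting an extreme-copy-number locus depletes a neutral gene", {
  cfg <- sim_config(n_genes = 2L, guides_per_gene = 1L, frac_essential = 0,
                    n_intergenic_controls = 0L,
                    n_nontargeting_controls = 0L, t0_sdlog = 0,
                    cn_spec = list(frac_by_class = c(normal = 1, mid = 0,
                                                     extreme = 0),
                                   delta = 0.02, damage_min_copies = 8L),
                    seed = 6L)
  lib <- simulate_library(cfg)
  lib$truth$genes$copy_number <- c(8L, 2L)
  lib$guides$efficiency <- c(1, 1)
  ct <- simulate_screen(lib$guides, lib$truth, cfg, mode = "expected")
  ctn <- normalize_counts(ct)
  lfc <- log2_fold_change(ctn, "plasmid", "day45_r1", pseudocount = 0)
  # relative depletion against the neutral guide is exactly
  # 45 * delta * (8 - 2) = 5.4 doublings
  expect_equal(unname(lfc[1] - lfc[2]), -45 * 0.02 * 6, tolerance = 1e-9)
  expect_lt(lfc[1], lfc[2] - 2)  # function-independent dropout
})

test_that("companion tables reflect the configured structure", {
  cfg <- sim_config(n_genes = 120L, guides_per_gene = 3L,
                    n_intergenic_controls = 10L,
                    n_nontargeting_controls = 10L, n_cell_lines = 50L,
                    seed = 8L)
  lib <- simulate_library(cfg)
  comp <- simulate_companions(lib$truth, cfg)
  expect_equal(ncol(comp$ceres), 50L)
  expect_setequal(comp$expression$gene_id, lib$truth$genes$gene_id)

  # buffered duplicate families of essential fly genes get weak scores,
  # singleton orthologs inherit strong scores
  tr <- lib$truth
  fly_ess <- tr$genes$essential[match(tr$orthology$fly_gene,
                                      tr$genes$gene_id)]
  hf <- comp$human_fitness
  buf <- hf$score[fly_ess & tr$orthology$buffered]
  sing <- hf$score[fly_ess & !tr$orthology$buffered]
  expect_gt(mean(sing), mean(buf) + 5)

  # no unexpressed stratum => expression-anchored FDR identically zero
  cfg0 <- sim_config(n_genes = 60L, guides_per_gene = 3L,
                     n_intergenic_controls = 25L,
                     n_nontargeting_controls = 25L,
                     frac_unexpressed = 0, cells_per_guide = 200L,
                     read_depth_per_guide = 100, seed = 12L)
  res <- run_small_screen(cfg0)
  expect_true(all(res$curve$fdr == 0))
})
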