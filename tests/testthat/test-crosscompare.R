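.orth_fixture <- function() {
  orthology <- data.frame(
    fly_gene = c("f1", "f2", "f2", "f3", "f3", "f4"),
    human_gene = c("h1", "h2a", "h2b", "h3a", "h3b", "h4"),
    confidence = c("high", "high", "moderate", "high", "low", "high"),
    stringsAsFactors = FALSE)
  human_fitness <- data.frame(
    human_gene = c("h1", "h2a", "h2b", "h3a", "h3b", "h4"),
    score = c(7, 5, 12, 4, 30, 2),
    expressed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  list(orthology = orthology, human_fitness = human_fitness)
}

test_that("most essential expressed ortholog is selected", {
  fx <- .orth_fixture()
  # unique ortholog: chosen directly
  expect_equal(map_most_essential_ortholog("f1", fx$orthology,
                                           fx$human_fitness), "h1")
  # multiple orthologs, scores {5, 12}: the 12 wins
  expect_equal(map_most_essential_ortholog("f2", fx$orthology,
                                           fx$human_fitness), "h2b")
  # low-confidence ortholog ignored even though it scores 30
  expect_equal(map_most_essential_ortholog("f3", fx$orthology,
                                           fx$human_fitness), "h3a")
  # all orthologs unexpressed: none
  expect_true(is.na(map_most_essential_ortholog("f4", fx$orthology,
                                                fx$human_fitness)))
  expect_true(is.na(map_most_essential_ortholog("zz", fx$orthology,
                                                fx$human_fitness)))
})

test_that("expression filter never lowers the chosen ortholog's score", {
  fx <- .orth_fixture()
  for (g in c("f1", "f2", "f3", "f4")) {
    with_f <- map_most_essential_ortholog(g, fx$orthology,
                                          fx$human_fitness)
    no_f <- map_most_essential_ortholog(g, fx$orthology, fx$human_fitness,
                                        require_expressed = FALSE)
    if (!is.na(with_f)) {
      s <- function(h) fx$human_fitness$score[fx$human_fitness$human_gene
                                              == h]
      expect_gte(s(no_f), s(with_f))
      # the chosen ortholog is always expressed under the filter
      expect_true(fx$human_fitness$expressed[fx$human_fitness$human_gene
                                             == with_f])
    }
  }
})

test_that("cumulative essentiality is a running mean", {
  scores <- c(a = 3, b = 1, c = 2)
  expect_equal(cumulative_essentiality(c("a", "b", "c"), scores),
               c(3, 2, 2))
  expect_equal(cumulative_essentiality(rep("a", 4), scores), rep(3, 4))
  expect_error(cumulative_essentiality(c("a", "zz"), scores), "zz")
})

test_that("dependency counts are strict-threshold column counts", {
  ceres <- rbind(g1 = c(-1.2, -0.5, -0.9), g2 = c(0.1, 0.2, -0.1))
  colnames(ceres) <- paste0("line", 1:3)
  dc <- dependency_counts(c("g1", "g2", "g3"), ceres, cutoff = -0.8)
  expect_equal(dc$n_dependent_lines[dc$human_gene == "g1"], 2L)
  expect_equal(dc$n_dependent_lines[dc$human_gene == "g2"], 0L)
  expect_equal(attr(dc, "missing"), "g3")   # missing, not zero
  expect_equal(attr(dc, "n_cell_lines"), 3L)
})

test_that("copy-number bias summarizes depletion per bin", {
  # uniform copy number 2: every ratio is 1 by construction
  sc <- data.frame(gene_id = sprintf("g%02d", 1:20), z = rnorm(20))
  cn2 <- data.frame(gene_id = sc$gene_id, copy_number = 2L)
  cb <- copy_number_bias(sc, cn2)
  expect_true(is.na(attr(cb, "extreme_ratio")))  # empty extreme bin
  expect_equal(cb$ratio_vs_normal[1], 1)

  # constructed 1.8x extreme bin
  sc3 <- data.frame(gene_id = sprintf("g%02d", 1:30),
                    z = rep(c(-1, -1.8), c(20, 10)))
  cn3 <- data.frame(gene_id = sc3$gene_id,
                    copy_number = rep(c(2L, 9L), c(20, 10)))
  cb3 <- copy_number_bias(sc3, cn3)
  expect_equal(attr(cb3, "extreme_ratio"), 1.8)
  expect_equal(cb3$n_genes, c(20L, 0L, 10L))

  expect_error(copy_number_bias(sc3, cn3[1:5, ]), "copy numbers")
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  universe <- sprintf("u%02d", 1:20)
  terms <- list(all = universe, five = universe[1:5],
                none = universe[16:20])
  hits <- universe[1:10]
  res <- hypergeometric_enrichment(hits, terms, universe)
  expect_equal(res$p[res$term == "all"], 1)
  # overlap 5 of a 5-gene term: single-term upper tail
  expect_equal(res$p[res$term == "five"],
               choose(5, 5) * choose(15, 5) / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(res$overlap[res$term == "none"], 0L)
  expect_equal(res$p[res$term == "none"], 1)  # tail includes 0

  adj <- hypergeometric_enrichment(hits, terms, universe, adjust = TRUE)
  expect_equal(adj$p_adj, p.adjust(adj$p, "BH"))
  expect_error(hypergeometric_enrichment("zz", terms, universe),
               "outside")
  expect_error(hypergeometric_enrichment(hits, terms, character(0)),
               "empty universe")
})

test_that("overlap statistics are exact counts with a tail p", {
  universe <- letters[1:15]
  a <- letters[1:6]
  expect_equal(overlap_stats(a, a, universe)$fraction_of_a, 1)
  d <- overlap_stats(a, letters[7:9], universe)
  expect_equal(d$overlap, 0L)
  expect_equal(d$fraction_of_a, 0)
  expect_equal(d$p, 1)
  ov <- overlap_stats(letters[1:4], letters[3:8], universe)
  expect_equal(ov$overlap, 2L)
  expect_equal(ov$fraction_of_a, 0.5)
  expect_equal(ov$p, brute_hyper_upper(2, 15, 6, 4), tolerance = 1e-12)
  expect_error(overlap_stats(c("a", "zz"), a, universe), "zz")
})

test_that("multi-target amplicons are discarded and Z recomputed", {
  targets <- list(a1 = "g1", a2 = "g1", a3 = c("g2", "g3"), a4 = "g4",
                  a5 = c("g5", "g6", "g7"))
  scores <- c(a1 = -4, a2 = -2, a3 = -9, a4 = 0, a5 = 9)
  res <- rnai_offtarget_filter(targets, scores)
  expect_setequal(res$retained, c("a1", "a2", "a4"))
  expect_setequal(res$removed, c("a3", "a5"))
  # partition
  expect_setequal(c(res$retained, res$removed), names(targets))
  # screen-wide standardization over retained amplicons only
  x <- scores[res$retained]
  expect_equal(res$amplicon_z, (x - mean(x)) / sd(x))
  # gene score is the most extreme amplicon Z
  g1z <- res$gene_z$z[res$gene_z$gene_id == "g1"]
  expect_equal(g1z, max(abs(res$amplicon_z[c("a1", "a2")])) *
                 sign(res$amplicon_z["a1"]), ignore_attr = TRUE)
  # idempotent on the retained set
  res2 <- rnai_offtarget_filter(targets[res$retained], scores)
  expect_setequal(res2$retained, res$retained)
  expect_equal(res2$amplicon_z, res$amplicon_z)

  expect_error(rnai_offtarget_filter(list(a = character(0)), c(a = 1)),
               "non-empty")
  expect_error(rnai_offtarget_filter(list(a = c("g", "h")), c(a = 1)),
               "retained")
})

test_that("buffered paralog strata run below singleton strata", {
  cfg <- sim_config(n_genes = 300L, guides_per_gene = 3L,
                    n_intergenic_controls = 20L,
                    n_nontargeting_controls = 20L, seed = 77L)
  lib <- simulate_library(cfg)
  comp <- simulate_companions(lib$truth, cfg)
  tr <- lib$truth$genes
  hits <- tr$gene_id[tr$essential]      # oracle hits from the truth
  hf <- comp$human_fitness
  curves <- paralog_strata_curves(tr$gene_id, hits, comp$orthology, hf)
  gap <- paralog_buffering_gap(curves)
  expect_gt(gap, 0)
  # mapping never returns an unexpressed ortholog
  expect_true(all(hf$expressed[match(curves$mapping$human_gene,
                                     hf$human_gene)]))
})
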