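#' Configuration for an end-to-end screen analysis run
#'
#' Bundles the simulation configuration with every analysis-stage parameter
#' so a run is fully described by one object: the low-initial-count
#' percentile, normalization method, fold-change pseudocount, permutation
#' iterations, FDR threshold and variant, and the run mode (`basal` or
#' `differential`).  Precedence is caller > defaults; the complete resolved
#' configuration is recorded in the run manifest.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param mode `"basal"` or `"differential"`; differential mode requires a
#'   `drug_spec` in `sim`.
#' @param percentile Low-initial-count filter percentile.
#' @param normalization `"total"` or `"median_ratio"`.
#' @param pseudocount Fold-change pseudocount.
#' @param n_iter Permutation iterations for Z-scores.
#' @param alpha FDR threshold for hit calling.
#' @param rpkm_threshold Expression threshold anchoring the FDR.
#' @param fdr_variant `"main_text"` or `"legend_normalized"`.
#' @param benefit_threshold Basal-benefit cutoff for differential mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir,
                       mode = c("basal", "differential"),
                       percentile = 10, normalization = "total",
                       pseudocount = 0.5, n_iter = 1000L, alpha = 0.05,
                       rpkm_threshold = 1, fdr_variant = "main_text",
                       benefit_threshold = 2) {
  mode <- match.arg(mode)
  if (mode == "differential" && is.null(sim$drug_spec))
    stop("configuration error: differential mode requires a drug_spec in ",
         "the simulation configuration")
  structure(list(sim = sim, out_dir = out_dir, mode = mode,
                 percentile = percentile, normalization = normalization,
                 pseudocount = pseudocount, n_iter = as.integer(n_iter),
                 alpha = alpha, rpkm_threshold = rpkm_threshold,
                 fdr_variant = fdr_variant,
                 benefit_threshold = benefit_threshold),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  basename(path)
}

#' Run the full screen pipeline
#'
#' Orchestrates simulate -> count filter -> normalize -> fold-change ->
#' gene scores -> FDR -> hit list, writing every stage output as TSV plus a
#' machine-readable JSON manifest recording all parameters, the seed,
#' removed-guide logs, and an MD5 checksum per output file.  Rerunning the
#' same configuration reproduces byte-identical outputs.  In differential
#' mode the drug arm is scored against the no-treatment arm after removing
#' context-nonspecific beneficial guides.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`scores`, `curve`, `hits`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  lib <- simulate_library(config$sim)
  files <- c(files, .write_tsv(lib$guides, out("guides.tsv")),
             .write_tsv(lib$truth$genes, out("truth_genes.tsv")))
  ct <- simulate_screen(lib$guides, lib$truth, config$sim,
                        include_drug_arms = config$mode == "differential")
  write_count_table(ct, out("counts.tsv"))
  files <- c(files, "counts.tsv")

  ctf <- filter_low_initial(ct, percentile = config$percentile)
  files <- c(files, .write_tsv(attr(ctf, "removed"),
                               out("removed_guides.tsv")))
  ctn <- normalize_counts(ctf, method = config$normalization)

  basal_samples <- ctn$samples$sample_id[ctn$samples$condition == "none" &
                                         ctn$samples$timepoint > 0]
  lfc_basal <- average_lfc(lapply(basal_samples, function(s)
    log2_fold_change(ctn, "plasmid", s, config$pseudocount)))
  files <- c(files, .write_tsv(
    data.frame(guide_id = names(lfc_basal), lfc = lfc_basal),
    out("lfc_basal.tsv")))

  if (config$mode == "basal") {
    scores <- score_genes(lfc_basal, ctn$guides, n_iter = config$n_iter,
                          seed = config$sim$seed + 7L)
  } else {
    drug_name <- config$sim$drug_spec$name
    drug_samples <- ctn$samples$sample_id[ctn$samples$condition ==
                                          drug_name]
    lfc_drug <- average_lfc(lapply(drug_samples, function(s)
      log2_fold_change(ctn, "plasmid", s, config$pseudocount)))
    files <- c(files, .write_tsv(
      data.frame(guide_id = names(lfc_drug), lfc = lfc_drug),
      out("lfc_drug.tsv")))
    scores <- differential_score(lfc_drug, lfc_basal, ctn$guides,
                                 benefit_threshold =
                                   config$benefit_threshold,
                                 n_iter = config$n_iter,
                                 seed = config$sim$seed + 7L)
  }
  files <- c(files, .write_tsv(scores, out("scores.tsv")))

  companions <- simulate_companions(lib$truth, config$sim)
  curve <- rankwise_fdr(scores, companions$expression,
                        rpkm_threshold = config$rpkm_threshold,
                        variant = config$fdr_variant)
  hits <- call_hits(curve, config$alpha)
  files <- c(files, .write_tsv(as.data.frame(curve), out("fdr.tsv")))
  writeLines(hits, out("hits.txt"))
  files <- c(files, "hits.txt")

  manifest <- list(
    package = "dropscreen",
    mode = config$mode,
    seed = config$sim$seed,
    parameters = list(
      n_genes = config$sim$n_genes,
      frac_essential = config$sim$frac_essential,
      guides_per_gene = config$sim$guides_per_gene,
      total_days = config$sim$total_days,
      cells_per_guide = config$sim$cells_per_guide,
      read_depth_per_guide = config$sim$read_depth_per_guide,
      percentile = config$percentile,
      normalization = config$normalization,
      pseudocount = config$pseudocount,
      n_iter = config$n_iter,
      alpha = config$alpha,
      rpkm_threshold = config$rpkm_threshold,
      fdr_variant = config$fdr_variant,
      benefit_threshold = config$benefit_threshold),
    n_guides_removed = nrow(attr(ctf, "removed")),
    n_hits = length(hits),
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(manifest = manifest, guides = lib$guides,
                 truth = lib$truth, counts = ct, lfc = lfc_basal,
                 scores = scores, curve = curve, hits = hits,
                 companions = companions))
}
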