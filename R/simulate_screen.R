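#' Simulate a pooled dropout screen
#'
#' Generates a guide x sample count table with the statistical structure of a
#' pooled knockout fitness screen.  The generative model is deliberately
#' simple enough to admit closed-form expectations:
#'
#' * Each guide `i` starts from a log-normal plasmid abundance; the t = 0
#'   sample is a multinomial sequencing draw from the plasmid pool (the
#'   screen's t = 0 readcounts come from the plasmid library).
#' * Cells are seeded multinomially at `cells_per_guide * n_guides` and each
#'   cell is edited once, at integration, with probability equal to its
#'   guide's efficiency.
#' * Per doubling, an unedited cell multiplies by 2; an edited cell carrying
#'   a guide against gene `g` multiplies by `2^(1 + beta_g - penalty)`, where
#'   the copy-number penalty is `delta * max(0, c_g - 2)` for genes at or
#'   above the configured extreme-amplification threshold (cutting a highly
#'   amplified locus depresses growth regardless of gene function) and 0
#'   otherwise.
#' * Every `passage_interval_days` the population is resampled multinomially
#'   back to the bottleneck size; after the final interval the sample is
#'   sequenced as a multinomial draw of `read_depth_per_guide * n_guides`
#'   reads over guide abundances.
#'
#' Replicates share the plasmid pool but use independent seeding, passaging,
#' and sequencing randomness.  In `mode = "expected"` all sampling is
#' replaced by expectations (real-valued counts, no bottleneck noise), which
#' makes limiting cases exactly checkable: e.g. a fully edited guide on a
#' gene with `beta = -1` has expected abundance ratio `2^-T` relative to a
#' neutral guide after `T` doublings.
#'
#' If the configuration has a `drug_spec` and `include_drug_arms = TRUE`,
#' two additional samples per replicate are produced: the drug arm grows
#' drug-free for `integration_days`, then for `treatment_days` with each
#' gene's context effect (`beta + beta_drug` for resistance/synergy genes)
#' applied.  The basal samples double as the no-treatment control arm since
#' `integration_days + treatment_days = total_days`.
#'
#' @param guides Guide table from [simulate_library()].
#' @param truth Truth list from [simulate_library()].
#' @param config The [sim_config()] used.
#' @param mode `"stochastic"` (integer counts, sampling noise) or
#'   `"expected"` (real-valued expectations, no sampling).
#' @param n_replicates Number of final-timepoint replicates.
#' @param include_drug_arms Whether to simulate the drug arm (requires
#'   `config$drug_spec`).
#' @param seed RNG seed for the screen; defaults to `config$seed + 1` so the
#'   library and the screen have distinct but reproducible streams.
#' @return A [count_table()] with a `plasmid` sample (timepoint 0) and one
#'   `dayD_rR` sample per replicate (plus `drug_rR` samples if requested).
#' @export
simulate_screen <- function(guides, truth, config,
                            mode = c("stochastic", "expected"),
                            n_replicates = 2L,
                            include_drug_arms = !is.null(config$drug_spec),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  if (!all(stats::na.omit(guides$gene_id) %in% truth$genes$gene_id))
    stop("truth does not cover all guides")
  if (config$read_depth_per_guide <= 0 || config$cells_per_guide <= 0)
    stop("sequencing depth and population size must be positive")
  set.seed(if (is.null(seed)) config$seed + 1L else seed)

  n_guides <- nrow(guides)
  gidx <- match(guides$gene_id, truth$genes$gene_id)
  beta <- ifelse(is.na(gidx), 0, truth$genes$beta[gidx])
  cn <- ifelse(is.na(gidx), 2L, truth$genes$copy_number[gidx])
  delta <- config$cn_spec$delta
  dmg_min <- config$cn_spec$damage_min_copies
  penalty <- ifelse(cn >= dmg_min, delta * pmax(0, cn - 2), 0)
  # non-targeting guides never cut, so they escape the copy-number penalty
  penalty[guides$control_class == "non_targeting"] <- 0
  beta_basal <- beta - penalty
  eff <- guides$efficiency

  beta_drug <- beta_basal
  if (include_drug_arms) {
    if (is.null(config$drug_spec))
      stop("include_drug_arms requires a drug_spec in the configuration")
    dmap <- match(guides$gene_id, truth$drug$gene_id)
    beta_drug <- beta_basal +
      ifelse(is.na(dmap), 0, truth$drug$beta_drug[dmap])
  }

  # plasmid pool and t0 sequencing
  plasmid <- stats::rlnorm(n_guides, meanlog = 0, sdlog = config$t0_sdlog)
  p0 <- plasmid / sum(plasmid)
  depth <- round(config$read_depth_per_guide * n_guides)
  t0_counts <- if (mode == "expected") depth * p0 else
    as.numeric(stats::rmultinom(1L, depth, p0))

  n_cells <- config$cells_per_guide * n_guides
  d_per_pass <- config$doublings_per_day * config$passage_interval_days

  grow_phase <- function(edited, unedited, beta_eff, days) {
    n_pass <- round(days / config$passage_interval_days)
    fe <- 2^(d_per_pass * (1 + beta_eff))
    fu <- 2^d_per_pass
    for (p in seq_len(n_pass)) {
      edited <- edited * fe
      unedited <- unedited * fu
      if (mode == "stochastic") {
        pool <- c(edited, unedited)
        drawn <- as.numeric(stats::rmultinom(1L, n_cells, pool / sum(pool)))
        edited <- drawn[seq_len(n_guides)]
        unedited <- drawn[n_guides + seq_len(n_guides)]
      } else {
        tot <- sum(edited) + sum(unedited)
        edited <- edited * n_cells / tot
        unedited <- unedited * n_cells / tot
      }
    }
    list(edited = edited, unedited = unedited)
  }

  sequence_pop <- function(edited, unedited) {
    ab <- edited + unedited
    if (mode == "expected") depth * ab / sum(ab) else
      as.numeric(stats::rmultinom(1L, depth, ab / sum(ab)))
  }

  seed_cells <- function() {
    if (mode == "expected") {
      n0 <- n_cells * p0
      list(edited = n0 * eff, unedited = n0 * (1 - eff))
    } else {
      n0 <- as.numeric(stats::rmultinom(1L, n_cells, p0))
      ed <- stats::rbinom(n_guides, n0, eff)
      list(edited = ed, unedited = n0 - ed)
    }
  }

  samples <- data.frame(sample_id = "plasmid", timepoint = 0,
                        replicate = 0L, condition = "none",
                        stringsAsFactors = FALSE)
  cols <- list(t0_counts)
  for (r in seq_len(n_replicates)) {
    s0 <- seed_cells()
    basal <- grow_phase(s0$edited, s0$unedited, beta_basal,
                        config$total_days)
    cols <- c(cols, list(sequence_pop(basal$edited, basal$unedited)))
    samples <- rbind(samples, data.frame(
      sample_id = sprintf("day%g_r%d", config$total_days, r),
      timepoint = config$total_days, replicate = r, condition = "none",
      stringsAsFactors = FALSE))
    if (include_drug_arms) {
      ds <- config$drug_spec
      s0d <- seed_cells()
      ph1 <- grow_phase(s0d$edited, s0d$unedited, beta_basal,
                        ds$integration_days)
      ph2 <- grow_phase(ph1$edited, ph1$unedited, beta_drug,
                        ds$treatment_days)
      cols <- c(cols, list(sequence_pop(ph2$edited, ph2$unedited)))
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_r%d", ds$name, r),
        timepoint = config$total_days, replicate = r, condition = ds$name,
        stringsAsFactors = FALSE))
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- guides$guide_id
  count_table(counts, guides, samples)
}
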