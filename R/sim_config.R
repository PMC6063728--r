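#' Default nucleotide position weight matrix for guide efficiency
#'
#' A 21 x 4 matrix of additive log-odds weights used by the synthetic-data
#' generator to turn a guide's sequence into an editing efficiency.  Rows are
#' the 20 protospacer positions (5' to 3') plus the first, unconstrained PAM
#' base (position 21); columns are the bases A, C, G, T.  The default encodes
#' the qualitative preferences reported for SpCas9 knockout reagents: a strong
#' preference for G and against T at the PAM-proximal protospacer end, milder
#' C preferences inside the seed region, a G preference at the 5' end, and a
#' variable first PAM base that is mildly informative.  Efficiency is
#' `plogis(sum of weights + noise)`, so an all-zero matrix yields efficiency
#' 0.5 for every guide.
#'
#' @return Numeric 21 x 4 matrix with columns `A`, `C`, `G`, `T`.
#' @export
default_efficiency_pwm <- function() {
  pwm <- matrix(0, nrow = 21L, ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[1L, "G"] <- 1.0
  pwm[14L, "T"] <- -1.0
  pwm[16L, "C"] <- 1.0
  pwm[18L, "C"] <- 1.5
  pwm[20L, "G"] <- 2.0
  pwm[20L, "T"] <- -1.5
  pwm[21L, "C"] <- -1.0
  pwm[21L, "G"] <- 1.0
  pwm
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("invalid sim_config field '", name, "': must be a fraction in [0, 1]",
         call. = FALSE)
  x
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop("invalid sim_config field '", name, "': must be an integer >= ", min,
         call. = FALSE)
  as.integer(x)
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop("invalid sim_config field '", name, "': must be > 0", call. = FALSE)
  x
}

#' Configuration for a synthetic pooled CRISPR dropout screen
#'
#' Collects every parameter of the synthetic screen generator.  The defaults
#' describe the screen regime the package emulates: genome-scale knockout
#' libraries with 6 guides per gene and shared intergenic plus non-targeting
#' negative controls, cells doubling roughly once per day, passaged every 5
#' days for 45 days at a bottleneck of 1500 cells per guide, sequenced to a
#' mean depth of 500 reads per guide, with the t = 0 sample taken from the
#' plasmid pool.  Ten percent of genes are fitness genes with per-doubling
#' deficits drawn uniformly from \[-1, -0.2\]; a quarter of the non-fitness
#' genes are unexpressed (RPKM < 1), which anchors the expression-based FDR
#' downstream.
#'
#' @param n_genes Number of targeted genes.
#' @param frac_essential Fraction of genes that are true fitness genes.
#' @param effect_range Length-2 numeric, the (negative) uniform range of the
#'   per-doubling fitness deficit `beta` for fitness genes.
#' @param guides_per_gene Guides designed per gene.
#' @param n_intergenic_controls,n_nontargeting_controls Numbers of
#'   cutting-but-neutral (intergenic) and non-cutting negative control guides
#'   shared across sublibraries.
#' @param pwm 21 x 4 position weight matrix driving guide editing efficiency
#'   (see [default_efficiency_pwm()]).
#' @param efficiency_noise_sd Standard deviation of the Gaussian noise added
#'   to the per-guide weight sum before the logistic transform.
#' @param doublings_per_day Cell doublings per day for unedited cells.
#' @param passage_interval_days Days between passaging bottlenecks.
#' @param total_days Total screen duration in days.
#' @param cells_per_guide Cells carried per guide at each passage (bottleneck
#'   size is `cells_per_guide * n_guides`).
#' @param read_depth_per_guide Mean sequencing reads per guide per sample.
#' @param t0_sdlog Log-normal `sdlog` of plasmid-pool guide abundance (the
#'   dispersion of the t = 0 representation).
#' @param frac_unexpressed Fraction of non-fitness genes with RPKM < 1.
#' @param paralog_spec List with `frac_paralog` (fraction of genes whose
#'   simulated human ortholog set is a buffered duplicate family) and
#'   `family_size` (orthologs per family).
#' @param cn_spec List describing copy-number structure: `frac_by_class`
#'   (named fractions for copy-number classes `normal` = 1-2 copies,
#'   `mid` = 3-7, `extreme` = >= 8; 3% of genes are extreme), `delta`
#'   (per-extra-copy, per-doubling growth penalty applied independently of
#'   gene function), and `damage_min_copies` (the copy number at or above
#'   which the cutting penalty applies; default 8, i.e. only extreme
#'   amplifications incur function-independent dropout).  The default
#'   `delta = 1.5e-4` is calibrated so that, under the default screen
#'   conditions, extreme-copy-number genes show a ~1.8-fold mean-depletion
#'   bias on the gene Z scale relative to normal-copy genes.
#' @param drug_spec Optional list describing a drug arm: `name`,
#'   `integration_days` (drug-free window while guides integrate),
#'   `treatment_days`, `n_resistance`, `n_synergy`, `beta_resistance`
#'   (context effect > 0: knockout grows faster under drug), `beta_synergy`
#'   (context effect < 0).  `integration_days + treatment_days` must equal
#'   `total_days` so the basal arm doubles as the no-treatment control.
#' @param n_cell_lines Number of pseudo cell lines in the simulated
#'   CERES-style dependency matrix.
#' @param seed Integer RNG seed; identical configurations (including the
#'   seed) reproduce identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       frac_essential = 0.10,
                       effect_range = c(-1, -0.2),
                       guides_per_gene = 6L,
                       n_intergenic_controls = 250L,
                       n_nontargeting_controls = 250L,
                       pwm = default_efficiency_pwm(),
                       efficiency_noise_sd = 0.3,
                       doublings_per_day = 1,
                       passage_interval_days = 5,
                       total_days = 45,
                       cells_per_guide = 1500L,
                       read_depth_per_guide = 500,
                       t0_sdlog = 0.5,
                       frac_unexpressed = 0.25,
                       paralog_spec = list(frac_paralog = 0.35,
                                           family_size = 2L),
                       cn_spec = list(frac_by_class = c(normal = 0.85,
                                                        mid = 0.12,
                                                        extreme = 0.03),
                                      delta = 1.5e-4,
                                      damage_min_copies = 8L),
                       drug_spec = NULL,
                       n_cell_lines = 436L,
                       seed = 1L) {
  cfg <- list(
    n_genes = .check_count(n_genes, "n_genes"),
    frac_essential = .check_fraction(frac_essential, "frac_essential"),
    effect_range = effect_range,
    guides_per_gene = .check_count(guides_per_gene, "guides_per_gene"),
    n_intergenic_controls = .check_count(n_intergenic_controls,
                                         "n_intergenic_controls", min = 0L),
    n_nontargeting_controls = .check_count(n_nontargeting_controls,
                                           "n_nontargeting_controls",
                                           min = 0L),
    pwm = pwm,
    efficiency_noise_sd = efficiency_noise_sd,
    doublings_per_day = .check_positive(doublings_per_day,
                                        "doublings_per_day"),
    passage_interval_days = .check_positive(passage_interval_days,
                                            "passage_interval_days"),
    total_days = .check_positive(total_days, "total_days"),
    cells_per_guide = .check_count(cells_per_guide, "cells_per_guide"),
    read_depth_per_guide = .check_positive(read_depth_per_guide,
                                           "read_depth_per_guide"),
    t0_sdlog = t0_sdlog,
    frac_unexpressed = .check_fraction(frac_unexpressed, "frac_unexpressed"),
    paralog_spec = paralog_spec,
    cn_spec = cn_spec,
    drug_spec = drug_spec,
    n_cell_lines = .check_count(n_cell_lines, "n_cell_lines"),
    seed = .check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(cfg$effect_range) || length(cfg$effect_range) != 2L ||
      any(cfg$effect_range > 0))
    stop("invalid sim_config field 'effect_range': fitness effects must be ",
         "<= 0 in the basal screen", call. = FALSE)
  cfg$effect_range <- sort(cfg$effect_range)
  if (!is.matrix(cfg$pwm) || !identical(dim(cfg$pwm), c(21L, 4L)))
    stop("invalid sim_config field 'pwm': must be a 21 x 4 matrix",
         call. = FALSE)
  colnames(cfg$pwm) <- c("A", "C", "G", "T")
  if (!is.numeric(cfg$efficiency_noise_sd) || cfg$efficiency_noise_sd < 0)
    stop("invalid sim_config field 'efficiency_noise_sd': must be >= 0",
         call. = FALSE)
  if (!is.numeric(cfg$t0_sdlog) || cfg$t0_sdlog < 0)
    stop("invalid sim_config field 't0_sdlog': must be >= 0", call. = FALSE)
  .check_fraction(cfg$paralog_spec$frac_paralog, "paralog_spec$frac_paralog")
  .check_count(cfg$paralog_spec$family_size, "paralog_spec$family_size",
               min = 2L)
  fr <- cfg$cn_spec$frac_by_class
  if (is.null(fr) || !all(c("normal", "mid", "extreme") %in% names(fr)) ||
      abs(sum(fr) - 1) > 1e-8)
    stop("invalid sim_config field 'cn_spec$frac_by_class': named fractions ",
         "for classes normal/mid/extreme summing to 1", call. = FALSE)
  if (is.null(cfg$cn_spec$delta) || cfg$cn_spec$delta < 0)
    stop("invalid sim_config field 'cn_spec$delta': must be >= 0",
         call. = FALSE)
  cfg$cn_spec$damage_min_copies <-
    .check_count(cfg$cn_spec$damage_min_copies %||% 8L,
                 "cn_spec$damage_min_copies", min = 3L)
  if (!is.null(cfg$drug_spec)) {
    ds <- cfg$drug_spec
    ds$name <- ds$name %||% "drug"
    ds$integration_days <- ds$integration_days %||% 15
    ds$treatment_days <- ds$treatment_days %||% 30
    ds$n_resistance <- ds$n_resistance %||% 10L
    ds$n_synergy <- ds$n_synergy %||% 10L
    ds$beta_resistance <- ds$beta_resistance %||% 0.3
    ds$beta_synergy <- ds$beta_synergy %||% -0.5
    if (abs(ds$integration_days + ds$treatment_days - cfg$total_days) > 1e-8)
      stop("invalid sim_config field 'drug_spec': integration_days + ",
           "treatment_days must equal total_days", call. = FALSE)
    cfg$drug_spec <- ds
  }
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
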