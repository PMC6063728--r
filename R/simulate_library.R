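#' Guide editing efficiency from sequence
#'
#' Computes the editing efficiency of each guide as the logistic transform of
#' the sum of position-weight-matrix entries over its 21-nucleotide context
#' (20-nt protospacer plus the first PAM base), optionally plus Gaussian
#' noise already folded into `offset`.
#'
#' @param seq21 Character vector of 21-letter sequences (protospacer + first
#'   PAM base).
#' @param pwm 21 x 4 weight matrix with columns `A`, `C`, `G`, `T`.
#' @param offset Numeric vector (recycled) added to the weight sum before the
#'   logistic transform; used for per-guide noise.
#' @return Numeric vector of efficiencies in (0, 1).
#' @export
guide_efficiency <- function(seq21, pwm, offset = 0) {
  stopifnot(is.matrix(pwm), identical(dim(pwm), c(21L, 4L)))
  if (any(nchar(seq21) != 21L))
    stop("guide sequences must be 21 letters (protospacer + first PAM base)")
  chars <- matrix(unlist(strsplit(seq21, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seq21), ncol = 21L, byrow = TRUE)
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("guide sequences must use the alphabet A/C/G/T")
  idx <- matrix(idx, nrow = nrow(chars))
  w <- vapply(seq_len(nrow(idx)),
              function(i) sum(pwm[cbind(1:21, idx[i, ])]),
              numeric(1))
  stats::plogis(w + offset)
}

.random_dna <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
}

#' Simulate a guide library and its ground truth
#'
#' Generates a synthetic knockout library with `guides_per_gene` random
#' 20-nt protospacers per gene (PAM `NGG`), plus intergenic and non-targeting
#' negative controls, together with the full ground truth needed to grade
#' downstream analysis: per-gene fitness effects, expression (RPKM), copy
#' numbers, simulated human orthologs with paralog-buffering structure,
#' optional drug-context effects, and per-guide editing efficiencies driven
#' by the configured position weight matrix.
#'
#' Genes are split round-robin across three sublibrary groups; control guides
#' are shared (`sublibrary = "common"`).  True fitness genes always have
#' RPKM >= 1 (an unexpressed gene cannot be a fitness gene); a configurable
#' fraction of the remaining genes is unexpressed, which is what anchors the
#' expression-based FDR.
#'
#' @param config A [sim_config()] object.
#' @return A list with `guides` (data frame: `guide_id`, `protospacer`,
#'   `pam`, `gene_id` (`NA` for controls), `sublibrary`, `control_class`,
#'   `efficiency`) and `truth` (list with `genes` data frame, `orthology`,
#'   `drug`, and the `config` used).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  n_ess <- round(config$frac_essential * n)
  essential <- rep(FALSE, n)
  essential[sample.int(n, n_ess)] <- TRUE
  beta <- numeric(n)
  beta[essential] <- stats::runif(n_ess, config$effect_range[1],
                                  config$effect_range[2])

  # expression: fitness genes are always expressed; a configured fraction of
  # the neutral genes is unexpressed (RPKM < 1)
  rpkm <- pmax(stats::rlnorm(n, meanlog = log(20), sdlog = 1.2), 1.001)
  neutral_idx <- which(!essential)
  n_unexpr <- round(config$frac_unexpressed * length(neutral_idx))
  unexpr <- sample(neutral_idx, n_unexpr)
  rpkm[unexpr] <- stats::runif(n_unexpr, 0.001, 0.999)

  # copy number classes: normal 1-2, mid 3-7, extreme >= 8
  fr <- config$cn_spec$frac_by_class
  cls <- sample(c("normal", "mid", "extreme"), n, replace = TRUE,
                prob = fr[c("normal", "mid", "extreme")])
  copy_number <- integer(n)
  copy_number[cls == "normal"] <- sample(1:2, sum(cls == "normal"),
                                         replace = TRUE, prob = c(0.1, 0.9))
  copy_number[cls == "mid"] <- sample(3:7, sum(cls == "mid"), replace = TRUE)
  copy_number[cls == "extreme"] <- sample(8:10, sum(cls == "extreme"),
                                          replace = TRUE)

  # simulated human orthology: a fraction of genes map to a duplicated
  # (buffered) family; the rest map to a single ortholog
  has_paralog <- stats::runif(n) < config$paralog_spec$frac_paralog
  fam_size <- config$paralog_spec$family_size
  orth <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- if (has_paralog[i]) fam_size else 1L
    data.frame(fly_gene = gene_id[i],
               human_gene = sprintf("HS_%s_%d", gene_id[i], seq_len(k)),
               confidence = "high",
               buffered = has_paralog[i],
               stringsAsFactors = FALSE)
  }))

  # drug-context effects on expressed neutral genes
  drug <- NULL
  if (!is.null(config$drug_spec)) {
    ds <- config$drug_spec
    pool <- setdiff(which(!essential), unexpr)
    pick <- sample(pool, ds$n_resistance + ds$n_synergy)
    drug <- data.frame(
      gene_id = gene_id[pick],
      class = rep(c("resistance", "synergy"),
                  c(ds$n_resistance, ds$n_synergy)),
      beta_drug = rep(c(ds$beta_resistance, ds$beta_synergy),
                      c(ds$n_resistance, ds$n_synergy)),
      stringsAsFactors = FALSE)
  }

  genes <- data.frame(gene_id = gene_id, beta = beta, essential = essential,
                      rpkm = rpkm, copy_number = copy_number,
                      cn_class = cls, has_paralog = has_paralog,
                      stringsAsFactors = FALSE)

  g_per <- config$guides_per_gene
  n_t <- n * g_per
  targeting <- data.frame(
    guide_id = sprintf("%s_sg%d", rep(gene_id, each = g_per),
                       rep(seq_len(g_per), n)),
    protospacer = .random_dna(n_t, 20L),
    pam = paste0(.random_dna(n_t, 1L), "GG"),
    gene_id = rep(gene_id, each = g_per),
    sublibrary = rep(paste0("group", (seq_len(n) - 1L) %% 3L + 1L),
                     each = g_per),
    control_class = "targeting",
    stringsAsFactors = FALSE)

  make_controls <- function(n_ctrl, prefix, class) {
    if (n_ctrl == 0L) return(NULL)
    data.frame(guide_id = sprintf("%s_%04d", prefix, seq_len(n_ctrl)),
               protospacer = .random_dna(n_ctrl, 20L),
               pam = paste0(.random_dna(n_ctrl, 1L), "GG"),
               gene_id = NA_character_, sublibrary = "common",
               control_class = class, stringsAsFactors = FALSE)
  }
  guides <- rbind(targeting,
                  make_controls(config$n_intergenic_controls, "ctrl_int",
                                "intergenic"),
                  make_controls(config$n_nontargeting_controls, "ctrl_nt",
                                "non_targeting"))

  noise <- if (config$efficiency_noise_sd > 0)
    stats::rnorm(nrow(guides), 0, config$efficiency_noise_sd) else 0
  guides$efficiency <- guide_efficiency(
    paste0(guides$protospacer, substr(guides$pam, 1L, 1L)),
    config$pwm, offset = noise)

  list(guides = guides,
       truth = list(genes = genes, orthology = orth, drug = drug,
                    config = config))
}
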