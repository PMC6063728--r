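#' Simulate companion tables for cross-species and quality analyses
#'
#' Emits the side tables the downstream comparative analyses consume, keyed
#' consistently with the simulated guide library's genes:
#'
#' * `expression`: gene -> RPKM (fitness genes always RPKM >= 1).
#' * `orthology`: fly gene -> simulated human ortholog(s) with a confidence
#'   label and the buffered-duplicate flag.
#' * `human_fitness`: per simulated human gene, a fitness score on the
#'   negative-Bayes-factor scale (larger = more essential) plus an
#'   `expressed` flag.  Orthologs of fly fitness genes inherit strong scores
#'   when they are singletons; members of a buffered duplicate family each
#'   receive weak single-knockout scores (redundancy masks the phenotype).
#' * `ceres`: human gene x pseudo-cell-line matrix of CERES-style dependency
#'   scores (more negative = more essential), `n_cell_lines` columns.
#' * `copy_number`: gene -> copy number.
#' * `term_sets`: named list of gene sets emulating annotation terms --
#'   two essential-complex analogs (ribosome-like, proteasome-like), a
#'   neutral complex (peroxisome-like), and a random set.
#'
#' @param truth Truth list from [simulate_library()].
#' @param config The [sim_config()] used.
#' @return Named list of the tables above.
#' @export
simulate_companions <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- truth$genes
  orth <- truth$orthology

  expression <- data.frame(gene_id = genes$gene_id, rpkm = genes$rpkm,
                           stringsAsFactors = FALSE)

  fly_ess <- genes$essential[match(orth$fly_gene, genes$gene_id)]
  n_h <- nrow(orth)
  score <- numeric(n_h)
  score[fly_ess & !orth$buffered] <- stats::rnorm(sum(fly_ess &
                                                      !orth$buffered), 15, 3)
  score[fly_ess & orth$buffered] <- stats::rnorm(sum(fly_ess &
                                                     orth$buffered), 0.5, 1)
  score[!fly_ess] <- stats::rnorm(sum(!fly_ess), 0, 2)
  human_fitness <- data.frame(
    human_gene = orth$human_gene, score = score,
    expressed = stats::runif(n_h) < 0.9, stringsAsFactors = FALSE)

  mu <- numeric(n_h)
  mu[fly_ess & !orth$buffered] <- -1.2
  mu[fly_ess & orth$buffered] <- -0.15
  ceres <- matrix(stats::rnorm(n_h * config$n_cell_lines, mean = mu,
                               sd = 0.3),
                  nrow = n_h, ncol = config$n_cell_lines,
                  dimnames = list(orth$human_gene,
                                  sprintf("line%03d",
                                          seq_len(config$n_cell_lines))))

  copy_number <- data.frame(gene_id = genes$gene_id,
                            copy_number = genes$copy_number,
                            stringsAsFactors = FALSE)

  ess_genes <- genes$gene_id[genes$essential]
  neut_expr <- genes$gene_id[!genes$essential & genes$rpkm >= 1]
  take <- function(pool, k) sample(pool, min(k, length(pool)))
  ribo <- take(ess_genes, 40L)
  prot <- take(setdiff(ess_genes, ribo), 30L)
  term_sets <- list(
    ribosome_like = ribo,
    proteasome_like = prot,
    peroxisome_like = take(neut_expr, 30L),
    random_set = take(genes$gene_id, 40L))

  list(expression = expression, orthology = orth[, c("fly_gene",
                                                     "human_gene",
                                                     "confidence")],
       human_fitness = human_fitness, ceres = ceres,
       copy_number = copy_number, term_sets = term_sets)
}

#' Simulate amplicon reads for a sequenced sample
#'
#' Builds synthetic single-end amplicon reads matching the screen's
#' sequencing layout -- a 1-9 nt random stagger, a 6 nt inline sublibrary
#' barcode, the constant annealing sequence, then the 20 nt protospacer and
#' the start of the tracrRNA scaffold -- so the demultiplexer can be
#' exercised without external data.
#'
#' @param counts Named integer vector: reads per guide id.
#' @param guides Guide table (needs `guide_id`, `protospacer`).
#' @param spec An [amplicon_spec()].
#' @param barcode The 6 nt barcode to embed (one sample per barcode).
#' @param frac_junk Fraction of additional junk reads lacking the annealing
#'   sequence (these must come out unassigned).
#' @return Character vector of read sequences, shuffled.
#' @export
simulate_amplicon_reads <- function(counts, guides, spec, barcode,
                                    frac_junk = 0) {
  stopifnot(all(names(counts) %in% guides$guide_id))
  proto <- guides$protospacer[match(names(counts), guides$guide_id)]
  reads <- unlist(lapply(seq_along(counts), function(i) {
    k <- counts[[i]]
    if (k == 0L) return(character(0))
    stagger <- vapply(sample(spec$stagger_range, k, replace = TRUE),
                      function(w) paste(sample(c("A", "C", "G", "T"), w,
                                               replace = TRUE),
                                        collapse = ""), character(1))
    paste0(stagger, barcode, spec$anneal, proto[i], spec$scaffold_prefix)
  }), use.names = FALSE)
  n_junk <- round(frac_junk * length(reads))
  if (n_junk > 0)
    reads <- c(reads, .random_dna(n_junk, 50L))
  sample(reads)
}
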