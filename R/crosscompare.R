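#' Map a fly gene to its most essential expressed human ortholog
#'
#' Among a fly gene's human orthologs at high or moderate mapping
#' confidence, restricted to those expressed in the human cell line, returns
#' the ortholog with the maximal fitness score (larger = more essential,
#' negative-Bayes-factor scale).  A gene with a unique expressed ortholog
#' maps to it directly; a gene with no expressed ortholog maps to nothing
#' and is excluded from downstream curves.
#'
#' @param fly_gene Fly gene id.
#' @param orthology Data frame `fly_gene`, `human_gene`, `confidence`
#'   (levels `high`/`moderate`/`low`).
#' @param human_fitness Data frame `human_gene`, `score`, `expressed`.
#' @param confidences Accepted confidence levels (default high + moderate).
#' @param require_expressed Drop unexpressed orthologs (default `TRUE`).
#' @return The chosen human gene id, or `NA_character_` if none.
#' @export
map_most_essential_ortholog <- function(fly_gene, orthology, human_fitness,
                                        confidences = c("high", "moderate"),
                                        require_expressed = TRUE) {
  cand <- orthology[orthology$fly_gene == fly_gene &
                    orthology$confidence %in% confidences, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  m <- match(cand$human_gene, human_fitness$human_gene)
  cand <- cand[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  if (require_expressed) {
    keep <- human_fitness$expressed[m]
    cand <- cand[keep, , drop = FALSE]
    m <- m[keep]
  }
  if (nrow(cand) == 0L) return(NA_character_)
  cand$human_gene[which.max(human_fitness$score[m])]
}

#' Cumulative average essentiality curve
#'
#' `curve[k]` is the mean fitness score of the first `k` genes of an ordered
#' list -- the standard display for comparing strata such as paralog versus
#' singleton orthologs of fitness genes.
#'
#' @param gene_ids Ordered character vector of gene ids.
#' @param scores Named numeric vector (gene id -> fitness score) covering
#'   every listed gene.
#' @return Numeric vector of running means, same length as `gene_ids`.
#' @export
cumulative_essentiality <- function(gene_ids, scores) {
  x <- scores[gene_ids]
  if (anyNA(x)) stop("missing score for: ",
                     paste(gene_ids[is.na(x)], collapse = ", "))
  unname(cumsum(x) / seq_along(x))
}

#' Count dependent cell lines per gene in a CERES-style matrix
#'
#' A gene registers a fitness call in a cell line when its dependency score
#' is strictly below `cutoff` (CERES convention: more negative = more
#' essential; the default cutoff of -0.8 is configurable).
#'
#' @param genes Character vector of human gene ids.
#' @param ceres Numeric matrix, genes x cell lines.
#' @param cutoff Fitness-call threshold (strict `<`).
#' @return Data frame `human_gene`, `n_dependent_lines`; genes absent from
#'   the matrix are reported in the `"missing"` attribute, not counted as 0.
#' @export
dependency_counts <- function(genes, ceres, cutoff = -0.8) {
  stopifnot(is.finite(cutoff))
  present <- genes %in% rownames(ceres)
  counts <- rowSums(ceres[genes[present], , drop = FALSE] < cutoff)
  out <- data.frame(human_gene = genes[present],
                    n_dependent_lines = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- genes[!present]
  attr(out, "n_cell_lines") <- ncol(ceres)
  out
}

#' Copy-number bias of a fitness screen
#'
#' Summarizes dropout strength per copy-number bin -- normal (1-2 copies),
#' intermediate (3 to `extreme_cn - 1`), and extreme (`>= extreme_cn`,
#' default 8) -- as the mean depletion magnitude `mean(|min(Z, 0)|)` and
#' the hit rate per bin, plus each bin's ratio to the normal bin.  A
#' function-independent amplification bias shows up as an extreme-bin ratio
#' well above 1 while the intermediate bin stays near 1.
#'
#' @param scores Data frame with `gene_id`, `z`.
#' @param copy_number Data frame with `gene_id`, `copy_number` (integers
#'   >= 1).
#' @param hits Optional character vector of hit genes for the per-bin hit
#'   rate.
#' @param extreme_cn Copy number defining the extreme bin (default 8).
#' @return Data frame (`bin`, `n_genes`, `mean_depletion`, `hit_rate`,
#'   `ratio_vs_normal`); the extreme/normal ratio in attribute
#'   `"extreme_ratio"`.
#' @export
copy_number_bias <- function(scores, copy_number, hits = character(0),
                             extreme_cn = 8L) {
  cn <- copy_number$copy_number[match(scores$gene_id,
                                      copy_number$gene_id)]
  if (anyNA(cn) || any(cn < 1)) stop("copy numbers must cover all scored ",
                                     "genes and be >= 1")
  bin <- cut(cn, breaks = c(0, 2, extreme_cn - 1L, Inf),
             labels = c("1-2", paste0("3-", extreme_cn - 1L),
                        paste0(">=", extreme_cn)))
  depl <- abs(pmin(scores$z, 0))
  is_hit <- scores$gene_id %in% hits
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    data.frame(bin = b, n_genes = sum(i),
               mean_depletion = if (any(i)) mean(depl[i]) else NA_real_,
               hit_rate = if (any(i)) mean(is_hit[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$ratio_vs_normal <- out$mean_depletion / out$mean_depletion[1L]
  attr(out, "extreme_ratio") <- out$ratio_vs_normal[nrow(out)]
  out
}

#' Hypergeometric enrichment of a hit set over term sets
#'
#' For each term, with population = |universe|, successes = |term inside
#' universe|, draws = |hits|, and overlap x, reports the exact upper-tail
#' enrichment p-value `P(X >= x)`.  P-values are raw by default; set
#' `adjust = TRUE` for Benjamini-Hochberg adjustment across terms.
#'
#' @param hits Character vector of hit genes (must be within `universe`).
#' @param term_sets Named list of character vectors (term -> genes); each
#'   set is intersected with the universe.
#' @param universe Character vector, the gene universe.
#' @param adjust Apply BH adjustment (default `FALSE`).
#' @return Data frame: `term`, `term_size`, `overlap`, `p` (and `p_adj`).
#' @export
hypergeometric_enrichment <- function(hits, term_sets, universe,
                                      adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  bad <- setdiff(hits, universe)
  if (length(bad) > 0L) stop("hits outside the universe: ",
                             paste(bad, collapse = ", "))
  hits <- unique(hits)
  out <- do.call(rbind, lapply(names(term_sets), function(tm) {
    term <- intersect(term_sets[[tm]], universe)
    ov <- length(intersect(term, hits))
    data.frame(term = tm, term_size = length(term), overlap = ov,
               p = .hyper_upper(ov, length(universe), length(term),
                                length(hits)),
               stringsAsFactors = FALSE)
  }))
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Overlap statistics between two gene sets
#'
#' @param a,b Character vectors, both subsets of `universe` (violations are
#'   an error listing the offending genes).
#' @param universe Character vector, the gene universe.
#' @return List with `overlap` (|A intersect B|), `fraction_of_a`, and the
#'   exact hypergeometric upper-tail `p`.
#' @export
overlap_stats <- function(a, b, universe) {
  universe <- unique(universe)
  for (nm in c("a", "b")) {
    s <- get(nm)
    bad <- setdiff(s, universe)
    if (length(bad) > 0L)
      stop("set '", nm, "' not a subset of the universe; offenders: ",
           paste(bad, collapse = ", "))
  }
  a <- unique(a); b <- unique(b)
  ov <- length(intersect(a, b))
  list(overlap = ov,
       fraction_of_a = if (length(a) == 0L) NA_real_ else ov / length(a),
       p = .hyper_upper(ov, length(universe), length(b), length(a)))
}

#' Filter multi-target RNAi amplicons and re-standardize scores
#'
#' Retains only amplicons with exactly one unique target (multi-target
#' designs act through off-target effects and are discarded), then
#' recomputes a screen-wide Z for the retained amplicons as
#' `(score - mean) / sd` over the retained set.  The gene-level score is the
#' most extreme amplicon Z per target gene (convention flagged in the
#' output).  Retained plus removed amplicons partition the input, and the
#' operation is idempotent.
#'
#' @param amplicon_targets Named list: amplicon id -> character vector of
#'   unique target genes (non-empty).
#' @param amplicon_scores Named numeric vector of raw per-amplicon scores.
#' @return List with `retained`, `removed` (amplicon ids), `amplicon_z`
#'   (named vector over retained amplicons), and `gene_z` (data frame
#'   `gene_id`, `z`, `n_amplicons`, `convention`).
#' @export
rnai_offtarget_filter <- function(amplicon_targets, amplicon_scores) {
  if (any(lengths(amplicon_targets) == 0L))
    stop("every amplicon must have a non-empty target list")
  n_targets <- lengths(lapply(amplicon_targets, unique))
  retained <- names(amplicon_targets)[n_targets == 1L]
  removed <- names(amplicon_targets)[n_targets > 1L]
  if (length(retained) == 0L) stop("no single-target amplicons retained")
  x <- amplicon_scores[retained]
  z <- (x - mean(x)) / stats::sd(x)
  gene <- vapply(amplicon_targets[retained], `[[`, character(1), 1L)
  gene_z <- do.call(rbind, lapply(split(z, gene), function(v)
    data.frame(z = v[which.max(abs(v))], n_amplicons = length(v))))
  gene_z <- data.frame(gene_id = rownames(gene_z), gene_z,
                       convention = "most_extreme_amplicon_z",
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = retained, removed = removed, amplicon_z = z,
       gene_z = gene_z)
}
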