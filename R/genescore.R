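#' Maximum-likelihood gene effect from guide log2 fold-changes
#'
#' Under a Normal model in which guide `i` of a gene measures a common gene
#' effect `beta` with variance `v_i`, the MLE of `beta` is the
#' precision-weighted mean `sum(x/v) / sum(1/v)`; with equal variances this
#' reduces to the arithmetic mean of the guide log2 fold-changes.
#'
#' @param lfc Numeric vector of guide log2 fold-changes (>= 1 value).
#' @param variances Optional positive variances per guide; `NULL` = equal.
#' @return The effect estimate `beta_hat`.
#' @export
fit_gene_effect <- function(lfc, variances = NULL) {
  if (length(lfc) == 0L) stop("cannot fit a gene effect from zero guides")
  if (is.null(variances)) return(mean(lfc))
  stopifnot(length(variances) == length(lfc), all(variances > 0))
  sum(lfc / variances) / sum(1 / variances)
}

#' Permutation Z-scores against a negative-control null
#'
#' Standardizes per-gene effect estimates against a null built by resampling
#' size-matched guide sets from the negative-control guides: for each
#' distinct guide count `n`, `n_iter` sets of `n` control log2 fold-changes
#' are drawn (without replacement within a set) and averaged, giving the
#' null mean `mu(n)` and standard deviation `sigma(n)`; then
#' `Z = (beta_hat - mu(n)) / sigma(n)`.  Size-matching avoids bias between
#' genes measured by different numbers of guides.  A degenerate null
#' (`sigma = 0`) is floored at `sigma_floor`.  Genes are ranked by ascending
#' Z (rank 1 = most depleted), ties broken by gene id.
#'
#' @param effects Data frame with `gene_id`, `beta`, `n_guides`.
#' @param control_lfc Numeric vector of negative-control guide log2
#'   fold-changes (>= 20 required).
#' @param n_iter Resampling iterations (default 1000, >= 100 required).
#' @param seed Optional seed making the resampling deterministic.
#' @param sigma_floor Lower bound for the null standard deviation.
#' @return Data frame: `gene_id`, `beta`, `z`, `n_guides`, `rank`.
#' @export
zscore_permutation <- function(effects, control_lfc, n_iter = 1000L,
                               seed = NULL, sigma_floor = 1e-8) {
  stopifnot(all(c("gene_id", "beta", "n_guides") %in% names(effects)))
  if (length(control_lfc) < 20L)
    stop("need at least 20 control guides to build the permutation null")
  if (n_iter < 100L) stop("n_iter must be >= 100")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sizes <- sort(unique(effects$n_guides))
  mu <- sigma <- stats::setNames(numeric(length(sizes)), sizes)
  for (n in sizes) {
    if (n > length(control_lfc))
      stop("gene with more guides (", n, ") than available controls")
    means <- vapply(seq_len(n_iter), function(i)
      mean(control_lfc[sample.int(length(control_lfc), n)]), numeric(1))
    mu[as.character(n)] <- mean(means)
    sigma[as.character(n)] <- max(stats::sd(means), sigma_floor)
  }
  key <- as.character(effects$n_guides)
  z <- (effects$beta - mu[key]) / sigma[key]
  ord <- order(z, effects$gene_id)
  rank <- integer(length(z))
  rank[ord] <- seq_along(z)
  data.frame(gene_id = effects$gene_id, beta = effects$beta, z = unname(z),
             n_guides = effects$n_guides, rank = rank,
             stringsAsFactors = FALSE)
}

#' Score genes from guide log2 fold-changes
#'
#' Convenience wrapper: splits `lfc` into targeting guides (aggregated per
#' gene with [fit_gene_effect()]) and negative-control guides (the
#' permutation null), then calls [zscore_permutation()].  Genes whose guides
#' were all removed upstream are absent from the result (reported via the
#' `"unscored"` attribute), not given Z = 0; genes with a single usable
#' guide are flagged in the `few_guides` column.
#'
#' @param lfc Named per-guide log2 fold-change vector.
#' @param guides Guide annotation (needs `guide_id`, `gene_id`,
#'   `control_class`).
#' @param n_iter,seed,sigma_floor Passed to [zscore_permutation()].
#' @param control_classes Which control classes form the null (default both
#'   intergenic and non-targeting; restrict to one if desired).
#' @return Data frame as in [zscore_permutation()] plus `few_guides`.
#' @export
score_genes <- function(lfc, guides, n_iter = 1000L, seed = NULL,
                        sigma_floor = 1e-8,
                        control_classes = c("intergenic", "non_targeting")) {
  guides <- guides[match(names(lfc), guides$guide_id), , drop = FALSE]
  if (anyNA(guides$guide_id))
    stop("lfc contains guides absent from the annotation")
  is_ctrl <- guides$control_class %in% control_classes
  control_lfc <- lfc[is_ctrl]
  tgt <- !is_ctrl & !is.na(guides$gene_id)
  eff <- stats::aggregate(lfc[tgt], list(gene_id = guides$gene_id[tgt]),
                          function(x) c(beta = mean(x), n = length(x)))
  effects <- data.frame(gene_id = eff$gene_id, beta = eff$x[, "beta"],
                        n_guides = as.integer(eff$x[, "n"]),
                        stringsAsFactors = FALSE)
  out <- zscore_permutation(effects, control_lfc, n_iter = n_iter,
                            seed = seed, sigma_floor = sigma_floor)
  out$few_guides <- out$n_guides < 2L
  attr(out, "unscored") <- setdiff(unique(stats::na.omit(guides$gene_id)),
                                   out$gene_id)
  out
}

#' Differential (drug vs no-treatment) gene scores
#'
#' Computes per-guide differentials `delta = lfc_drug - lfc_none` after
#' excluding context-nonspecific beneficial guides
#' ([remove_context_nonspecific()]), then aggregates and standardizes them
#' exactly as the basal scoring does, using the control guides'
#' differentials as the null.  Positive Z = resistance (guide enriched under
#' drug relative to no treatment), negative Z = synergy/synthetic lethality.
#'
#' @param lfc_drug,lfc_none Named per-guide log2 fold-change vectors over
#'   the same guides.
#' @param guides Guide annotation.
#' @param benefit_threshold Basal-benefit cutoff passed to
#'   [remove_context_nonspecific()] (default `Inf` = keep all).
#' @param n_iter,seed Passed to [zscore_permutation()].
#' @return Data frame as in [score_genes()].
#' @export
differential_score <- function(lfc_drug, lfc_none, guides,
                               benefit_threshold = Inf, n_iter = 1000L,
                               seed = NULL) {
  if (!identical(sort(names(lfc_drug)), sort(names(lfc_none))))
    stop("drug and no-treatment arms must cover the same guides")
  lfc_none <- lfc_none[names(lfc_drug)]
  kept <- remove_context_nonspecific(lfc_none, benefit_threshold)$keep
  delta <- lfc_drug[kept] - lfc_none[kept]
  score_genes(delta, guides, n_iter = n_iter, seed = seed)
}

#' Pearson correlation of replicate gene scores
#'
#' @param a,b Named numeric score vectors (gene id -> score) sharing at
#'   least 3 genes.
#' @return Pearson's r over the shared gene universe.
#' @export
replicate_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  stats::cor(a[shared], b[shared], method = "pearson")
}
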