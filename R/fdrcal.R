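#' Expression-anchored rank-wise false-discovery rate
#'
#' Orders genes by ascending Z (most depleted first; ties broken by gene id)
#' and estimates, at every rank, the empirical FDR anchored on expression: a
#' phenotypic assertion for a gene with RPKM below `rpkm_threshold` is an
#' error, because an unexpressed gene cannot be a true fitness gene.  Two
#' variants are provided:
#'
#' * `"main_text"` (default): `fdr(r) = #errors among top r / r`, i.e.
#'   cumulative false positives over called positives.  This is the variant
#'   used for hit calling.
#' * `"legend_normalized"`: cumulative errors at rank `r` divided by the
#'   total number of RPKM-below-threshold genes in the universe.
#'
#' The raw empirical curve is reported; `monotone = TRUE` optionally applies
#' a running-minimum smoothing from the strongest rank (for plotting only).
#'
#' @param scores Data frame with `gene_id` and `z` (e.g. from
#'   [score_genes()]).
#' @param expression Data frame with `gene_id` and `rpkm`, covering every
#'   scored gene (missing genes are an error).
#' @param rpkm_threshold Expression threshold defining an error (default 1).
#' @param variant `"main_text"` or `"legend_normalized"`.
#' @param monotone Apply running-minimum smoothing (default `FALSE`).
#' @return A data frame of class `fdr_curve`: `rank`, `gene_id`, `z`,
#'   `rpkm`, `is_error`, `fdr`; attributes record the threshold and variant.
#' @export
rankwise_fdr <- function(scores, expression, rpkm_threshold = 1,
                         variant = c("main_text", "legend_normalized"),
                         monotone = FALSE) {
  variant <- match.arg(variant)
  if (nrow(scores) == 0L) stop("empty score list")
  rpkm <- expression$rpkm[match(scores$gene_id, expression$gene_id)]
  if (anyNA(rpkm))
    stop("missing expression values for: ",
         paste(scores$gene_id[is.na(rpkm)], collapse = ", "))
  ord <- order(scores$z, scores$gene_id)
  gene <- scores$gene_id[ord]
  z <- scores$z[ord]
  rpkm <- rpkm[ord]
  err <- rpkm < rpkm_threshold
  cum <- cumsum(err)
  r <- seq_along(gene)
  fdr <- if (variant == "main_text") cum / r else {
    tot <- sum(expression$rpkm[match(unique(scores$gene_id),
                                     expression$gene_id)] < rpkm_threshold)
    if (tot == 0) rep(0, length(r)) else cum / tot
  }
  # optional smoothing: each rank takes the minimum fdr achievable at or
  # beyond it, so the reported curve is non-decreasing toward weaker ranks
  if (monotone) fdr <- rev(cummin(rev(fdr)))
  out <- data.frame(rank = r, gene_id = gene, z = z, rpkm = rpkm,
                    is_error = err, fdr = pmin(pmax(fdr, 0), 1),
                    stringsAsFactors = FALSE)
  attr(out, "rpkm_threshold") <- rpkm_threshold
  attr(out, "variant") <- variant
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Call hits at an FDR threshold
#'
#' Hits are the genes at ranks `1..r*` where `r*` is the largest rank whose
#' estimated FDR is at most `alpha` (`r* = 0` gives an empty set).  Hit sets
#' are nested in `alpha` by construction.
#'
#' @param curve An [rankwise_fdr()] curve.
#' @param alpha FDR threshold in (0, 1\].
#' @return Character vector of hit gene ids (ordered by rank).
#' @export
call_hits <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "fdr_curve"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  ok <- which(curve$fdr <= alpha)
  if (length(ok) == 0L) return(character(0))
  curve$gene_id[seq_len(max(ok))]
}

#' ROC-style discovery curve against a gold-standard positive set
#'
#' Emits, at every rank of the FDR curve, the estimated FDR and the true
#' positive rate `TPR(r) = |positives among top r| / |positives|`, e.g. the
#' discovery rate of an essential complex's members as a function of FDR.
#'
#' @param curve An [rankwise_fdr()] curve.
#' @param positives Non-empty character vector of gold-standard genes
#'   (must be within the scored universe).
#' @return Data frame: `rank`, `fdr`, `tpr`.
#' @export
roc_vs_fdr <- function(curve, positives) {
  stopifnot(inherits(curve, "fdr_curve"))
  if (length(positives) == 0L) stop("empty positive set")
  missing <- setdiff(positives, curve$gene_id)
  if (length(missing) > 0L)
    stop("positives outside the scored universe: ",
         paste(missing, collapse = ", "))
  tpr <- cumsum(curve$gene_id %in% positives) / length(positives)
  data.frame(rank = curve$rank, fdr = curve$fdr, tpr = tpr)
}

#' True-positive rate at a fixed estimated FDR
#'
#' The fraction of the gold-standard positive set recovered among the hits
#' called at `alpha` (default 5% FDR).
#'
#' @inheritParams roc_vs_fdr
#' @param alpha FDR threshold for [call_hits()].
#' @return A fraction in \[0, 1\].
#' @export
tpr_at_fdr <- function(curve, positives, alpha = 0.05) {
  if (length(positives) == 0L) stop("empty positive set")
  hits <- call_hits(curve, alpha)
  length(intersect(hits, positives)) / length(positives)
}

#' Hit rate per expression quantile bin
#'
#' Among expressed genes (RPKM at or above the threshold), bins genes into
#' quantiles of log RPKM (deciles by default) and reports the hit fraction
#' per bin -- a flat profile indicates no expression-level bias in hit
#' calling; a monotone profile indicates bias toward highly expressed genes.
#'
#' @param hits Character vector of hit gene ids.
#' @param expression Data frame with `gene_id`, `rpkm`.
#' @param rpkm_threshold Genes below this are excluded (default 1).
#' @param n_bins Number of quantile bins (default 10 = deciles).
#' @return Data frame: `bin`, `n_genes`, `n_hits`, `hit_rate`.
#' @export
expression_bias_profile <- function(hits, expression, rpkm_threshold = 1,
                                    n_bins = 10L) {
  expr <- expression[expression$rpkm >= rpkm_threshold, , drop = FALSE]
  q <- stats::quantile(log10(expr$rpkm), probs = seq(0, 1,
                                                     length.out = n_bins + 1L))
  q[1] <- -Inf; q[length(q)] <- Inf
  bin <- cut(log10(expr$rpkm), breaks = unique(q), include.lowest = TRUE,
             labels = FALSE)
  is_hit <- expr$gene_id %in% hits
  agg <- stats::aggregate(cbind(n_genes = rep(1L, length(bin)),
                                n_hits = as.integer(is_hit)),
                          by = list(bin = bin), FUN = sum)
  agg$hit_rate <- agg$n_hits / agg$n_genes
  agg
}
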