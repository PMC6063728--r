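#' Cumulative essentiality curves for paralog / fitness strata
#'
#' Implements the fly-to-human buffering comparison: every fly gene is
#' mapped to its most essential expressed human ortholog
#' ([map_most_essential_ortholog()]); fly genes with more than one
#' high/moderate-confidence ortholog form the paralog stratum (a buffered
#' duplicate family), the rest the singleton stratum.  Crossing this with
#' fly fitness-hit status yields four strata; for each, genes are ordered by
#' descending human fitness score and the cumulative average essentiality
#' curve is returned.  Paralog buffering manifests as the paralog stratum of
#' fly-fitness orthologs running below the singleton stratum.
#'
#' @param fly_genes Character vector of fly genes to analyze.
#' @param hits Character vector of fly fitness hits.
#' @param orthology,human_fitness As in [map_most_essential_ortholog()].
#' @return List of four numeric curves (`hit_singleton`, `hit_paralog`,
#'   `nonhit_singleton`, `nonhit_paralog`) plus `mapping`, the per-gene
#'   assignment table.
#' @export
paralog_strata_curves <- function(fly_genes, hits, orthology,
                                  human_fitness) {
  conf <- orthology[orthology$confidence %in% c("high", "moderate"), ,
                    drop = FALSE]
  n_orth <- table(conf$fly_gene)
  chosen <- vapply(fly_genes, map_most_essential_ortholog, character(1),
                   orthology = orthology, human_fitness = human_fitness)
  mapping <- data.frame(
    fly_gene = fly_genes, human_gene = chosen,
    has_paralog = as.integer(n_orth[fly_genes]) > 1L,
    is_hit = fly_genes %in% hits, stringsAsFactors = FALSE)
  mapping <- mapping[!is.na(mapping$human_gene), , drop = FALSE]
  mapping$score <- human_fitness$score[match(mapping$human_gene,
                                             human_fitness$human_gene)]
  scores <- stats::setNames(human_fitness$score,
                            human_fitness$human_gene)
  stratum_curve <- function(hit, paralog) {
    g <- mapping[mapping$is_hit == hit &
                 mapping$has_paralog == paralog, , drop = FALSE]
    g <- g[order(-g$score, g$human_gene), , drop = FALSE]
    if (nrow(g) == 0L) return(numeric(0))
    cumulative_essentiality(g$human_gene, scores)
  }
  list(hit_singleton = stratum_curve(TRUE, FALSE),
       hit_paralog = stratum_curve(TRUE, TRUE),
       nonhit_singleton = stratum_curve(FALSE, FALSE),
       nonhit_paralog = stratum_curve(FALSE, TRUE),
       mapping = mapping)
}

#' Mean gap between singleton and paralog cumulative curves
#'
#' The mean, over the common curve length, of the singleton-stratum minus
#' paralog-stratum cumulative essentiality among orthologs of fly fitness
#' hits; positive values indicate paralog buffering.
#'
#' @param curves Output of [paralog_strata_curves()].
#' @return Numeric scalar (NA if either stratum is empty).
#' @export
paralog_buffering_gap <- function(curves) {
  k <- min(length(curves$hit_singleton), length(curves$hit_paralog))
  if (k == 0L) return(NA_real_)
  mean(curves$hit_singleton[seq_len(k)] - curves$hit_paralog[seq_len(k)])
}
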