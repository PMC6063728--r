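.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Enumerate sgRNA candidates in the first half of a CDS
#'
#' Finds all 20-mers adjacent to an `NGG` PAM, on both strands, whose
#' predicted cut site falls in the first half of the coding sequence.
#' Coordinates are 0-based half-open on the forward CDS strand; the cut site
#' lies between protospacer positions 17 and 18 (3 nt from the PAM), so a
#' forward-strand protospacer starting at `s` cuts at coordinate `s + 17`
#' and a reverse-strand protospacer whose PAM (`CCN` in forward-strand text)
#' starts at `p` cuts at `p + 6`.  A candidate is kept iff its cut
#' coordinate is strictly less than half the CDS length.
#'
#' @param cds Character scalar, the coding sequence (alphabet ACGT;
#'   ambiguity codes are rejected).  Length must be >= 23 nt.
#' @param gene_id Gene identifier attached to the candidates.
#' @return Data frame: `gene_id`, `protospacer`, `pam`, `strand`
#'   (`+`/`-`), `cut_site` (0-based forward-strand coordinate), `seed`
#'   (the 12 nt of the protospacer adjacent to the PAM).
#' @export
enumerate_candidates <- function(cds, gene_id = "gene") {
  cds <- toupper(as.character(cds))
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  L <- nchar(cds)
  if (L < 23L) stop("CDS must be at least 23 nt")
  half <- L / 2
  out <- list()
  # forward strand: protospacer at s..s+19 (0-based), PAM at s+20..s+22
  for (s in 0:(L - 23L)) {
    pam <- substr(cds, s + 21L, s + 23L)
    if (substr(pam, 2L, 3L) == "GG") {
      cut <- s + 17L
      if (cut < half)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gene_id,
          protospacer = substr(cds, s + 1L, s + 20L), pam = pam,
          strand = "+", cut_site = cut, stringsAsFactors = FALSE)
    }
  }
  # reverse strand: PAM appears as CCN in forward text at p..p+2 (0-based),
  # protospacer occupies p+3..p+22 and reads as the reverse complement
  for (p in 0:(L - 23L)) {
    if (substr(cds, p + 1L, p + 2L) == "CC") {
      cut <- p + 6L
      if (cut < half)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gene_id,
          protospacer = .revcomp(substr(cds, p + 4L, p + 23L)),
          pam = .revcomp(substr(cds, p + 1L, p + 3L)),
          strand = "-", cut_site = cut, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), protospacer = character(0),
                      pam = character(0), strand = character(0),
                      cut_site = integer(0), seed = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$seed <- substr(res$protospacer, 9L, 20L)
  res
}

.count_genome_matches <- function(patterns, genome) {
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  vapply(patterns, function(p) {
    fwd <- sum(Biostrings::vcountPattern(p, genome))
    rev <- sum(Biostrings::vcountPattern(.revcomp(p), genome))
    fwd + rev
  }, numeric(1))
}

#' Rank candidates and select the top guides per gene
#'
#' Applies pluggable boolean filters (efficiency and frame-shift criteria
#' live outside this package; the default passes everything), then ranks the
#' survivors of each gene by uniqueness of the 12 nt seed region
#' (genome-wide seed match count ascending), the number of potential
#' off-target sites (full protospacer match count ascending), and finally
#' gene-internal cut position as a deterministic tie-break, and emits the
#' top `k` per gene.  Genes with fewer than `k` survivors emit all of them
#' and are flagged.
#'
#' @param candidates Data frame from [enumerate_candidates()] (one or many
#'   genes).
#' @param genome Character vector / `DNAStringSet` of genome sequence(s)
#'   used to count seed and protospacer matches (both strands, overlapping
#'   occurrences counted).
#' @param filters List of predicate functions, each taking the candidate
#'   data frame and returning a logical vector.
#' @param k Guides to select per gene (1-20; genome-scale libraries
#'   typically use 6-8).
#' @return Data frame of selected guides with `seed_matches`,
#'   `offtarget_sites`, `rank_in_gene`, `short_gene` columns.
#' @export
rank_and_select <- function(candidates, genome, filters = list(), k = 8L) {
  if (k < 1L || k > 20L) stop("k must be in [1, 20]")
  keep <- rep(TRUE, nrow(candidates))
  for (f in filters) keep <- keep & f(candidates)
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(cbind(cand, seed_matches = numeric(0),
                                     offtarget_sites = numeric(0),
                                     rank_in_gene = integer(0),
                                     short_gene = logical(0)))
  cand$seed_matches <- .count_genome_matches(cand$seed, genome)
  cand$offtarget_sites <- .count_genome_matches(cand$protospacer, genome)
  res <- do.call(rbind, lapply(split(cand, cand$gene_id), function(g) {
    ord <- order(g$seed_matches, g$offtarget_sites, g$cut_site)
    g <- g[ord, , drop = FALSE]
    g$rank_in_gene <- seq_len(nrow(g))
    g$short_gene <- nrow(g) < k
    g[seq_len(min(k, nrow(g))), , drop = FALSE]
  }))
  rownames(res) <- NULL
  res
}

#' Split hit-gene guides into strongly depleted and unchanging sets
#'
#' Restricts guides to the genes called at a strict FDR (the `top_n`
#' strongest such genes, e.g. the top 500 at < 2% FDR), then classifies
#' them by their log2 fold-change: `good` = strongly depleted (lfc at or
#' below `good_cut`), `bad` = unchanging (|lfc| at or below `bad_band`).
#' The two sets are disjoint by construction; overlapping thresholds
#' (`good_cut > -bad_band`) are an error.
#'
#' @param lfc Named per-guide log2 fold-change vector.
#' @param guides Guide annotation (`guide_id`, `gene_id`).
#' @param curve An [rankwise_fdr()] curve.
#' @param top_n Maximum number of hit genes used (default 500).
#' @param strict_alpha Strict FDR for the gene universe (default 0.02).
#' @param good_cut Depletion threshold for good guides (default -1).
#' @param bad_band Absolute-change band for bad guides (default 0.25).
#' @return List with `good` and `bad` guide-id vectors and `genes`, the
#'   hit-gene universe used.
#' @export
classify_good_bad <- function(lfc, guides, curve, top_n = 500L,
                              strict_alpha = 0.02, good_cut = -1,
                              bad_band = 0.25) {
  if (good_cut > -bad_band)
    stop("overlapping thresholds: good_cut must be <= -bad_band")
  hit_genes <- call_hits(curve, strict_alpha)
  hit_genes <- hit_genes[seq_len(min(top_n, length(hit_genes)))]
  gmap <- guides$gene_id[match(names(lfc), guides$guide_id)]
  in_univ <- !is.na(gmap) & gmap %in% hit_genes
  x <- lfc[in_univ]
  list(good = names(x)[x <= good_cut],
       bad = names(x)[abs(x) <= bad_band],
       genes = hit_genes)
}

#' Hypergeometric nucleotide position matrix
#'
#' For each of 21 positions (the 20 protospacer positions 5' to 3' plus the
#' first PAM base) and each base, tests whether the base is enriched among
#' strongly depleted ("good") guide designs versus unchanging ("bad") ones.
#' With population = good + bad guides, successes = guides carrying the base
#' at that position, draws = |good|, and x = good guides carrying the base,
#' the enrichment tail is `P(X >= x)` and the depletion tail `P(X <= x)`
#' under the hypergeometric law (exact tail sums).  The signed score is
#' `-log10(p_enrichment)` when enrichment is the smaller tail (positive =
#' favored in good guides) and `+log10(p_depletion)` (negative) when
#' depletion is smaller; an exact tie of tails scores 0.  Swapping the good
#' and bad sets negates every score.
#'
#' @param good,bad Non-empty character vectors of 21-letter guide sequences
#'   (protospacer + first PAM base), e.g. built with [guide_context()].
#' @return Object of class `position_matrix`: list with `score` (21 x 4),
#'   `p_enrich`, `p_deplete`, `counts_good`, `counts_bad`.
#' @export
position_matrix <- function(good, bad) {
  if (length(good) == 0L || length(bad) == 0L)
    stop("good and bad guide sets must both be non-empty")
  if (any(nchar(c(good, bad)) != 21L))
    stop("all sequences must be 21 letters (protospacer + first PAM base)")
  bases <- c("A", "C", "G", "T")
  count_mat <- function(seqs) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = length(seqs), ncol = 21L, byrow = TRUE)
    vapply(bases, function(b) colSums(chars == b), numeric(21L))
  }
  cg <- count_mat(good)
  cb <- count_mat(bad)
  ng <- length(good); nb <- length(bad); pop <- ng + nb
  score <- p_enr <- p_dep <- matrix(0, 21L, 4L,
                                    dimnames = list(NULL, bases))
  for (p in 1:21) for (b in 1:4) {
    x <- cg[p, b]
    succ <- cg[p, b] + cb[p, b]
    pe <- .hyper_upper(x, pop, succ, ng)
    pd <- .hyper_lower(x, pop, succ, ng)
    p_enr[p, b] <- pe
    p_dep[p, b] <- pd
    score[p, b] <- if (pe < pd) -log10(pe) else if (pd < pe) log10(pd) else 0
  }
  structure(list(score = score, p_enrich = p_enr, p_deplete = p_dep,
                 counts_good = cg, counts_bad = cb,
                 n_good = ng, n_bad = nb),
            class = "position_matrix")
}

#' @export
print.position_matrix <- function(x, ...) {
  cat("position_matrix: 21 positions x 4 bases;", x$n_good, "good vs",
      x$n_bad, "bad guides\n")
  print(round(x$score, 2))
  invisible(x)
}

#' 21-nt sequence context (protospacer + first PAM base) for guides
#'
#' @param guides Guide table with `protospacer` (20 nt) and `pam` (3 nt).
#' @param guide_ids Optional subset of guide ids.
#' @return Named character vector of 21-letter sequences.
#' @export
guide_context <- function(guides, guide_ids = NULL) {
  if (!is.null(guide_ids))
    guides <- guides[match(guide_ids, guides$guide_id), , drop = FALSE]
  stats::setNames(paste0(guides$protospacer, substr(guides$pam, 1L, 1L)),
                  guides$guide_id)
}
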