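#' Amplicon structure for inline-barcoded guide sequencing
#'
#' Describes the read layout produced by the screen's two-step library PCR:
#' a variable 1-9 nt stagger, a 6 nt inline barcode identifying the
#' sublibrary/sample, a constant annealing sequence, then the 20 nt
#' protospacer followed by the tracrRNA scaffold.
#'
#' @param barcodes Named character vector: barcode sequence -> sample (or
#'   sublibrary) label.  All barcodes must be unique and equal length.
#' @param anneal Constant annealing sequence preceding the guide.
#' @param stagger_range Integer range of stagger lengths.
#' @param barcode_length Barcode length in nt.
#' @param guide_length Protospacer length in nt.
#' @param scaffold_prefix Constant sequence appended after the guide when
#'   simulating reads.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(barcodes,
                          anneal = "GTTTTCCTCAATACTTCGTTCG",
                          stagger_range = 1:9,
                          barcode_length = 6L,
                          guide_length = 20L,
                          scaffold_prefix = "GTTTAAGAGCTAAGCTGG") {
  if (length(barcodes) == 0L || anyDuplicated(barcodes))
    stop("barcodes must be non-empty and unique")
  if (any(nchar(names(barcodes) %||% barcodes) == 0L))
    stop("barcodes must be named")
  if (is.null(names(barcodes))) names(barcodes) <- barcodes
  if (any(nchar(barcodes) != barcode_length))
    stop("all barcodes must have length ", barcode_length)
  if (nchar(anneal) == 0L) stop("anneal sequence must be non-empty")
  structure(list(barcodes = barcodes, anneal = toupper(anneal),
                 stagger_range = stagger_range,
                 barcode_length = as.integer(barcode_length),
                 guide_length = as.integer(guide_length),
                 scaffold_prefix = scaffold_prefix),
            class = "amplicon_spec")
}

.hamming1 <- function(x, y) {
  # TRUE if x and y differ at no more than one position (equal lengths)
  sum(utf8ToInt(x) != utf8ToInt(y)) <= 1L
}

#' Demultiplex amplicon reads into a guide count table
#'
#' Structured re-implementation of inline-barcode demultiplexing: each read
#' is scanned for the constant annealing sequence; the 6 nt immediately
#' before it are read as the barcode and the 20 nt immediately after it as
#' the protospacer.  A read is assigned iff the barcode matches a configured
#' barcode (exactly, or within one mismatch when `barcode_mismatch = 1`) and
#' the protospacer exactly matches a library guide; otherwise it is counted
#' as unassigned.  Every read is therefore assigned to exactly one
#' (barcode, guide) cell or unassigned, and assigned + unassigned equals the
#' total read count.
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ
#'   file (read via Biostrings).
#' @param spec An [amplicon_spec()].
#' @param library Guide table with unique `protospacer` values (duplicates
#'   are an error: they would make assignment ambiguous).
#' @param barcode_mismatch 0 (exact, default) or 1; guide matching is always
#'   exact to avoid cross-mapping between library members.
#' @return List with `counts` (guides x barcodes integer matrix, columns
#'   named by the barcode labels) and `unassigned` (count).
#' @export
demultiplex <- function(reads, spec, library, barcode_mismatch = 0L) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (anyDuplicated(library$protospacer))
    stop("duplicate protospacers in library: ",
         paste(unique(library$protospacer[duplicated(library$protospacer)]),
               collapse = ", "))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  }
  reads <- toupper(reads)
  n_bc <- length(spec$barcodes)
  counts <- matrix(0L, nrow = nrow(library), ncol = n_bc,
                   dimnames = list(library$guide_id, names(spec$barcodes)))
  unassigned <- 0L
  bl <- spec$barcode_length
  gl <- spec$guide_length
  pos <- regexpr(spec$anneal, reads, fixed = TRUE)
  ok <- pos > bl  # anneal found with room for a full barcode before it
  end_anneal <- pos + nchar(spec$anneal) - 1L
  ok <- ok & (end_anneal + gl <= nchar(reads))
  unassigned <- unassigned + sum(!ok)
  if (any(ok)) {
    bc <- substr(reads[ok], pos[ok] - bl, pos[ok] - 1L)
    guide <- substr(reads[ok], end_anneal[ok] + 1L, end_anneal[ok] + gl)
    bi <- match(bc, spec$barcodes)
    if (barcode_mismatch >= 1L) {
      miss <- which(is.na(bi))
      for (m in miss) {
        hits <- which(vapply(spec$barcodes, .hamming1, logical(1), y = bc[m]))
        if (length(hits) == 1L) bi[m] <- hits
      }
    }
    gi <- match(guide, library$protospacer)
    good <- !is.na(bi) & !is.na(gi)
    unassigned <- unassigned + sum(!good)
    if (any(good)) {
      tab <- table(factor(gi[good], levels = seq_len(nrow(library))),
                   factor(bi[good], levels = seq_len(n_bc)))
      counts <- counts + as.integer(tab)
      dim(counts) <- c(nrow(library), n_bc)
      dimnames(counts) <- list(library$guide_id, names(spec$barcodes))
    }
  }
  list(counts = counts, unassigned = unassigned)
}

#' Remove guides with low initial representation
#'
#' Within each sublibrary, guides whose t = 0 (plasmid) readcount falls
#' strictly below the given percentile of that sublibrary's t = 0 counts are
#' removed from all samples.  The percentile is the linear-interpolation
#' sample quantile (R type 7).  The removed guides are recorded in the
#' `"removed"` attribute of the result, and the thresholds in
#' `"low_initial_thresholds"`; a table already filtered at the same
#' percentile passes through unchanged, making the operation idempotent.
#'
#' @param ct A [count_table()] containing a t = 0 sample.
#' @param percentile Percentile in \[0, 100\] (default 10).
#' @param t0 Name of the t = 0 sample column.
#' @return Filtered [count_table()] with attributes `removed` (data frame)
#'   and `low_initial_thresholds`.
#' @export
filter_low_initial <- function(ct, percentile = 10, t0 = "plasmid") {
  stopifnot(inherits(ct, "count_table"))
  if (percentile < 0 || percentile > 100)
    stop("percentile must be in [0, 100]")
  if (!t0 %in% colnames(ct$counts))
    stop("t0 sample '", t0, "' not present in count table")
  prev <- attr(ct, "low_initial_percentile")
  if (!is.null(prev) && isTRUE(all.equal(prev, percentile))) return(ct)
  t0c <- ct$counts[, t0]
  sub <- ct$guides$sublibrary
  keep <- rep(TRUE, nrow(ct$guides))
  thresholds <- c()
  for (s in unique(sub)) {
    i <- sub == s
    thr <- stats::quantile(t0c[i], percentile / 100, type = 7, names = FALSE)
    thresholds[s] <- thr
    keep[i] <- t0c[i] >= thr
  }
  removed <- data.frame(guide_id = ct$guides$guide_id[!keep],
                        sublibrary = sub[!keep], t0_count = t0c[!keep],
                        stringsAsFactors = FALSE)
  out <- count_table(ct$counts[keep, , drop = FALSE],
                     ct$guides[keep, , drop = FALSE], ct$samples)
  attr(out, "removed") <- removed
  attr(out, "low_initial_thresholds") <- thresholds
  attr(out, "low_initial_percentile") <- percentile
  out
}

#' Normalize a count table
#'
#' `"total"` scales every sample to the mean column sum; `"median_ratio"`
#' uses median-of-ratios size factors (the reference is the per-guide
#' geometric mean over samples, computed on guides with all-positive
#' counts).  Both leave a pair of proportional columns equal after
#' normalization.
#'
#' @param ct A [count_table()].
#' @param method `"total"` or `"median_ratio"`.
#' @return A [count_table()] with real-valued normalized counts; size
#'   factors in attribute `"size_factors"`.
#' @export
normalize_counts <- function(ct, method = c("total", "median_ratio")) {
  method <- match.arg(method)
  stopifnot(inherits(ct, "count_table"))
  counts <- ct$counts
  cs <- colSums(counts)
  if (any(cs == 0)) stop("cannot normalize: sample(s) with all-zero counts: ",
                         paste(colnames(counts)[cs == 0], collapse = ", "))
  if (method == "total") {
    sf <- cs / mean(cs)
  } else {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) stop("median_ratio normalization needs at least one ",
                        "guide with positive counts in every sample")
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2,
                function(x) exp(stats::median(log(x) - logref)))
  }
  norm <- sweep(counts, 2, sf, "/")
  out <- count_table(norm, ct$guides, ct$samples)
  attr(out, "size_factors") <- sf
  out
}

#' Per-guide log2 fold-change between two samples
#'
#' `log2((final + pseudocount) / (t0 + pseudocount))` on normalized counts.
#' The pseudocount (default 0.5) guards guides that drop to zero.
#'
#' @param ct A normalized [count_table()].
#' @param t0,final Sample names.
#' @param pseudocount Added to both numerator and denominator.
#' @return Named numeric vector of log2 fold-changes per guide.
#' @export
log2_fold_change <- function(ct, t0 = "plasmid", final, pseudocount = 0.5) {
  stopifnot(inherits(ct, "count_table"))
  for (s in c(t0, final))
    if (!s %in% colnames(ct$counts)) stop("sample '", s, "' not found")
  lfc <- log2((ct$counts[, final] + pseudocount) /
              (ct$counts[, t0] + pseudocount))
  stats::setNames(lfc, rownames(ct$counts))
}

#' Average per-guide log2 fold-changes across replicates
#'
#' @param lfc_list List of named log2 fold-change vectors over the same
#'   guides (e.g. one per replicate).
#' @return Named numeric vector, the per-guide mean.
#' @export
average_lfc <- function(lfc_list) {
  stopifnot(length(lfc_list) >= 1L)
  nm <- names(lfc_list[[1L]])
  for (v in lfc_list)
    if (!identical(names(v), nm)) stop("replicate fold-changes must cover ",
                                       "the same guides in the same order")
  rowMeans(do.call(cbind, lfc_list))
}

#' Exclude context-nonspecific beneficial guides from differential scoring
#'
#' For drug screens only: guides whose log2 fold-change in the no-treatment
#' arm exceeds `benefit_threshold` (i.e. guides that give a survival benefit
#' under normal growth) are removed before differential scoring, since their
#' behavior varies widely under selection regardless of the drug.
#'
#' @param basal_lfc Named log2 fold-change vector from the no-treatment arm.
#' @param benefit_threshold Guides with basal lfc strictly above this are
#'   dropped; `Inf` removes nothing.
#' @return List with `keep` (guide ids retained) and `removed` (guide ids).
#' @export
remove_context_nonspecific <- function(basal_lfc, benefit_threshold) {
  drop <- basal_lfc > benefit_threshold
  list(keep = names(basal_lfc)[!drop], removed = names(basal_lfc)[drop])
}
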