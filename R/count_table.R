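#' Guide-by-sample count table
#'
#' Lightweight container pairing a nonnegative count matrix (guides in rows,
#' samples in columns) with the guide annotation and per-sample metadata
#' (timepoint in days, replicate id, treatment condition).
#'
#' @param counts Numeric matrix, guides x samples, rownames = guide ids.
#' @param guides Data frame with at least `guide_id`, `gene_id`,
#'   `sublibrary`, `control_class`; one row per count-matrix row.
#' @param samples Data frame with `sample_id`, `timepoint`, `replicate`,
#'   `condition`; one row per count-matrix column.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, guides, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- guides$guide_id
  stopifnot(nrow(counts) == nrow(guides),
            identical(rownames(counts), guides$guide_id))
  if (any(counts < 0)) stop("count table must be nonnegative")
  if (anyDuplicated(samples$sample_id))
    stop("sample names must be unique")
  stopifnot(ncol(counts) == nrow(samples))
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, guides = guides, samples = samples),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples\n")
  cat("samples:", paste(x$samples$sample_id, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a count table in MAGeCK readcount layout
#'
#' The on-disk format is the conventional tab-separated readcount layout:
#' first column `sgRNA`, second column `gene` (control guides carry their
#' control class as a label), then one column of counts per sample.
#' `read_count_table()` needs the guide annotation to restore sublibrary and
#' control-class information, and a sample table to restore metadata;
#' without one, all samples default to unknown metadata.
#'
#' @param ct A [count_table()].
#' @param path File path.
#' @param guides Guide annotation data frame (as in [count_table()]).
#' @param samples Optional sample metadata data frame.
#' @return `write_count_table()` returns `path` invisibly;
#'   `read_count_table()` returns a [count_table()].
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(sgRNA = ct$guides$guide_id,
                   gene = ifelse(is.na(ct$guides$gene_id),
                                 ct$guides$control_class, ct$guides$gene_id),
                   ct$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path, guides, samples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$sgRNA
  guides <- guides[match(df$sgRNA, guides$guide_id), , drop = FALSE]
  if (anyNA(guides$guide_id))
    stop("count table contains guides absent from the annotation")
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(counts),
                          timepoint = NA_real_, replicate = NA_integer_,
                          condition = "none", stringsAsFactors = FALSE)
  count_table(counts, guides, samples)
}
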