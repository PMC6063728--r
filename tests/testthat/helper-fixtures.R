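# Shared fixtures and independent oracles used across test files.

# a small, fast screen configuration for unit tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 100L, guides_per_gene = 4L,
             n_intergenic_controls = 40L, n_nontargeting_controls = 40L,
             cells_per_guide = 300L, read_depth_per_guide = 200,
             seed = seed, ...)
}

# independent linear-interpolation (type 7) quantile implementation
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# brute-force hypergeometric tails from binomial coefficients only
brute_hyper_upper <- function(x, pop, succ, draws) {
  lo <- max(0, draws - (pop - succ)); hi <- min(succ, draws)
  if (x > hi) return(0)
  ks <- max(x, lo):hi
  sum(choose(succ, ks) * choose(pop - succ, draws - ks)) /
    choose(pop, draws)
}
brute_hyper_lower <- function(x, pop, succ, draws) {
  lo <- max(0, draws - (pop - succ)); hi <- min(succ, draws)
  if (x < lo) return(0)
  ks <- lo:min(x, hi)
  sum(choose(succ, ks) * choose(pop - succ, draws - ks)) /
    choose(pop, draws)
}

# count overlapping occurrences of `pat` in `txt` on both strands by a
# direct substring scan (oracle for seed/off-target counting)
brute_count_both_strands <- function(pat, txt) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  count1 <- function(p, s) {
    n <- 0L
    w <- nchar(p)
    for (i in seq_len(nchar(s) - w + 1L))
      if (substr(s, i, i + w - 1L) == p) n <- n + 1L
    n
  }
  count1(pat, txt) + count1(rc(pat), txt)
}

# tiny demultiplexing spec shared by readcount tests
test_spec <- function() {
  amplicon_spec(barcodes = c(s1 = "ACGTAC", s2 = "TTGGCA"),
                anneal = "GTTTTCCTCAATACTTCGTTCG")
}

# guide table with known protospacers for demux tests
test_library <- function(n = 5L) {
  set.seed(42)
  data.frame(guide_id = sprintf("gd%02d", seq_len(n)),
             protospacer = vapply(seq_len(n), function(i)
               paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                     collapse = ""), character(1)),
             pam = "AGG", gene_id = sprintf("gene%02d", seq_len(n)),
             sublibrary = "group1", control_class = "targeting",
             stringsAsFactors = FALSE)
}

# run one simulated screen end to end and return everything downstream
# analyses need; used by several test files
run_small_screen <- function(cfg) {
  lib <- simulate_library(cfg)
  ct <- simulate_screen(lib$guides, lib$truth, cfg)
  ctn <- normalize_counts(filter_low_initial(ct))
  finals <- ctn$samples$sample_id[ctn$samples$timepoint > 0 &
                                  ctn$samples$condition == "none"]
  lfc <- average_lfc(lapply(finals, function(s)
    log2_fold_change(ctn, "plasmid", s)))
  scores <- score_genes(lfc, ctn$guides, n_iter = 300L,
                        seed = cfg$seed + 5L)
  comp <- simulate_companions(lib$truth, cfg)
  curve <- rankwise_fdr(scores, comp$expression)
  list(lib = lib, ct = ct, ctn = ctn, lfc = lfc, scores = scores,
       companions = comp, curve = curve)
}
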