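# Exact hypergeometric tail probabilities, computed as explicit sums of
# point masses (no normal or saddlepoint approximation).  Parameterization:
# a population of `pop` items of which `succ` are successes; `draws` items
# drawn without replacement; X = number of successes drawn.

.hyper_upper <- function(x, pop, succ, draws) {
  # P(X >= x)
  hi <- min(succ, draws)
  if (x > hi) return(0)
  lo <- max(0L, draws - (pop - succ))
  sum(stats::dhyper(max(x, lo):hi, succ, pop - succ, draws))
}

.hyper_lower <- function(x, pop, succ, draws) {
  # P(X <= x)
  lo <- max(0L, draws - (pop - succ))
  if (x < lo) return(0)
  hi <- min(succ, draws)
  sum(stats::dhyper(lo:min(x, hi), succ, pop - succ, draws))
}
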