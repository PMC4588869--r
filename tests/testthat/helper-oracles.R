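# Independent brute-force oracles used across test files.

# Two-sided Mann-Whitney p by full enumeration of all labelings of the
# pooled (untied) values: twice the smaller tail of the U distribution,
# capped at 1.
enumerate_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_obs <- sum(outer(a, b, ">"))
  labelings <- utils::combn(m + n, m)
  u_all <- apply(labelings, 2, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  })
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Hypergeometric point/tail probability by brute-force enumeration: n
# windows of which a+b are significant; draw the a+c "inside ROI" label as
# a subset and count subsets carrying exactly (at least) a significant
# windows.
enumerate_table_probs <- function(a, b, c, d) {
  n <- a + b + c + d
  sig <- c(rep(TRUE, a + b), rep(FALSE, c + d))
  k <- a + c
  if (k == 0) {
    return(list(point = as.numeric(a == 0), tail = as.numeric(a == 0)))
  }
  subsets <- utils::combn(n, k)
  hits <- apply(subsets, 2, function(idx) sum(sig[idx]))
  list(point = mean(hits == a), tail = mean(hits >= a))
}

# small standard fixtures
make_design24 <- function() {
  group_design(sprintf("S%02d", 1:24), rep(1:4, each = 6))
}
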