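# Shared fixtures, built in code.

# k identical repetitions of a given RT vector
constant_block <- function(rts, k = 5) {
  rt_block(matrix(rep(rts, each = k), nrow = k))
}

# noiseless planted-chunk block at fixed head positions
noiseless_block <- function(condition, heads, N = 16, k = 5) {
  generate_block(N, k, condition, noise_spec(0, 0), heads = heads)
}

# long-format data frame for one block (io fixtures)
block_to_long <- function(m, subject = "s1", block = 1) {
  k <- nrow(m); N <- ncol(m)
  data.frame(subject = subject, block = block,
             sequence = rep(seq_len(k), times = N),
             item = rep(seq_len(N), each = k),
             rt = as.vector(m))
}

# brute-force pmf of the difference of two k-fold sums of uniform ranks,
# by exhaustive enumeration of all N^(2k) rank assignments
enumerate_diff_pmf <- function(N, k) {
  g <- as.matrix(expand.grid(rep(list(seq_len(N)), 2L * k)))
  d <- rowSums(g[, seq_len(k), drop = FALSE]) -
       rowSums(g[, k + seq_len(k), drop = FALSE])
  support <- seq.int(-k * (N - 1L), k * (N - 1L))
  counts <- tabulate(d - min(support) + 1L, nbins = length(support))
  list(support = support, pmf = counts / nrow(g))
}
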