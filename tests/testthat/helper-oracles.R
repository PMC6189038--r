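# Independent brute-force oracles used to validate the analytical routines.

# two-sample KS statistic by direct ECDF comparison
ks_stat_oracle <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
}

# exact two-sided p-value by enumeration of all C(n+m, n) group assignments
# (valid for tie-free data); p = P(D >= D_obs) under the permutation null
ks_exact_p_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  d_obs <- ks_stat_oracle(x, y)
  splits <- utils::combn(length(pooled), n)
  d_all <- apply(splits, 2, function(idx) {
    ks_stat_oracle(pooled[idx], pooled[-idx])
  })
  mean(d_all >= d_obs - 1e-12)
}

# AUC by explicit pair counting (ties count 1/2)
auc_pair_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# minimal well-formed library: 2 genes x 2 guides + 2 controls
tiny_library <- function() {
  guide_library(
    guide_id = c("gA1", "gA2", "gB1", "gB2", "c1", "c2"),
    sequence = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
                 "AAAACCCCGGGGTTTTACGT", "GTACGTACGTACGTACGTAC",
                 "CCCCAAAATTTTGGGGACGT", "TTTTGGGGCCCCAAAAACGT"),
    gene = c("A", "A", "B", "B", "", ""),
    is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}
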