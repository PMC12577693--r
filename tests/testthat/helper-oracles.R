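# Independent brute-force oracles used by unit and acceptance tests.

# Step-up BH by direct formula: cummin over p * n / i from the largest rank.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
wilcox_enum <- function(a, b) {
  n <- length(a) + length(b)
  vals <- c(a, b)
  r <- rank(vals)
  obs <- sum(r[seq_along(a)])
  combs <- utils::combn(n, length(a))
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Naive O(N*|S|) GSEA running sum.
gsea_oracle <- function(scores, set) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% set
  nr <- sum(abs(s[hit]))
  if (nr == 0) { s_w <- rep(1, length(s)); nr <- sum(hit) } else s_w <- abs(s)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) s_w[i] / nr else -1 / sum(!hit)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
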